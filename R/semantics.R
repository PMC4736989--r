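#' Semantic distance matrices
#'
#' The semantic distance calculator (SDC) is a pair of square symmetric
#' matrices scoring similarity between vertex types and between edge types.
#' Entries lie in \[-1, 1\]: 1 means the two types are semantically
#' identical, 0 unrelated, -1 opposite, with graded values in between
#' permitted (users typically derive them from a type hierarchy).  The
#' diagonal is always 1.  A type pair absent from a matrix scores 0
#' ("unrelated"), so target graphs carrying extra types need no matrix edits.
#'
#' @param vertex_matrix,edge_matrix square numeric matrices with identical
#'   row/column dimnames (type names)
#' @return an object of class `sdc_matrices`
#' @export
sdc_matrices <- function(vertex_matrix, edge_matrix) {
  check_sdc_matrix(vertex_matrix, "vertex")
  check_sdc_matrix(edge_matrix, "edge")
  structure(list(vertex = vertex_matrix, edge = edge_matrix),
            class = "sdc_matrices")
}

check_sdc_matrix <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m))) {
    stop(what, " matrix must have identical row and column type names", call. = FALSE)
  }
  if (any(m < -1 | m > 1)) {
    stop(what, " matrix has an entry outside [-1, 1]", call. = FALSE)
  }
  if (nrow(m) > 0 && any(abs(diag(m) - 1) > 1e-12)) {
    stop(what, " matrix diagonal must equal 1", call. = FALSE)
  }
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-12))) {
    stop(what, " matrix must be symmetric", call. = FALSE)
  }
  invisible(m)
}

#' @export
print.sdc_matrices <- function(x, ...) {
  cat(sprintf("sdc_matrices: %d vertex types, %d edge types\n",
              nrow(x$vertex), nrow(x$edge)))
  invisible(x)
}

#' Load semantic distance matrices from TSV
#'
#' Each file is a tab-separated matrix whose first row and first column hold
#' the type names.  Entries must lie in \[-1, 1\], the diagonal must be 1 and
#' the matrix symmetric; violations are rejected.
#'
#' @param vertex_path,edge_path TSV matrix files
#' @return an [sdc_matrices()] object
#' @export
load_sdc <- function(vertex_path, edge_path) {
  read_one <- function(p) {
    df <- utils::read.delim(p, row.names = 1, check.names = FALSE)
    as.matrix(df)
  }
  sdc_matrices(read_one(vertex_path), read_one(edge_path))
}

#' Save semantic distance matrices to TSV
#' @param matrices an [sdc_matrices()] object
#' @param vertex_path,edge_path output files
#' @export
save_sdc <- function(matrices, vertex_path, edge_path) {
  write_one <- function(m, p) {
    df <- as.data.frame(m, check.names = FALSE)
    utils::write.table(cbind(type = rownames(m), df), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_one(matrices$vertex, vertex_path)
  write_one(matrices$edge, edge_path)
  invisible(NULL)
}

#' Identity semantic distance matrices
#'
#' The canonical special case: each type is identical to itself (1) and
#' unrelated to every other type (0).
#'
#' @param vertex_types,edge_types non-empty character vectors of type names
#' @return an [sdc_matrices()] object
#' @export
identity_sdc <- function(vertex_types, edge_types) {
  mk <- function(types) {
    types <- sort(unique(as.character(types)))
    if (length(types) == 0) stop("type vocabulary must be non-empty", call. = FALSE)
    m <- diag(length(types))
    dimnames(m) <- list(types, types)
    m
  }
  sdc_matrices(mk(vertex_types), mk(edge_types))
}

#' Semantic score of one type pair
#'
#' Looks up the similarity of two type names in the vertex or edge matrix.
#' Missing types resolve to 0 ("unrelated") rather than an error.
#'
#' @param matrices an [sdc_matrices()] object
#' @param kind `"vertex"` or `"edge"`
#' @param a,b type names
#' @return a real in \[-1, 1\]
#' @export
score_pair <- function(matrices, kind = c("vertex", "edge"), a, b) {
  kind <- match.arg(kind)
  m <- matrices[[kind]]
  if (a %in% rownames(m) && b %in% colnames(m)) unname(m[a, b]) else {
    if (identical(a, b)) 1 else 0
  }
}

# Vectorised internal lookup used by the search hot path.
score_pairs_vec <- function(m, a, b) {
  ia <- match(a, rownames(m))
  ib <- match(b, colnames(m))
  out <- ifelse(a == b, 1, 0)
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) out[ok] <- m[cbind(ia[ok], ib[ok])]
  out
}

#' Semantic score (SS) of a complete mapping
#'
#' The semantic score of a mapping is the arithmetic mean of the pairwise
#' SDC scores over all its elements: the \eqn{|V(Q)|} (mapped vertex, query
#' vertex) type pairs and the \eqn{|E(Q)|} (mapped edge, query edge) type
#' pairs, so \eqn{n = |V(Q)| + |E(Q)|}.  SS lies in \[-1, 1\] and equals 1
#' exactly when every element pair is semantically identical.
#'
#' @param M a mapping as returned by [search_graph()] (fields `vertices`,
#'   `edges`: named character vectors query role -> target vertex id and
#'   query edge id -> target edge id)
#' @param Q the [query_graph()] that was searched
#' @param G the target [typed_graph()]
#' @param matrices an [sdc_matrices()] object
#' @return the semantic score, a real in \[-1, 1\]
#' @export
score_mapping <- function(M, Q, G, matrices) {
  if (!setequal(names(M$vertices), Q$vertices$role) ||
      !setequal(names(M$edges), Q$edges$id)) {
    stop("mapping does not completely assign the query's vertices and edges",
         call. = FALSE)
  }
  vt <- stats::setNames(G$vertices$type, G$vertices$id)
  et <- stats::setNames(G$edges$type, G$edges$id)
  qvt <- stats::setNames(Q$vertices$type, Q$vertices$role)
  qet <- stats::setNames(Q$edges$type, Q$edges$id)
  v_scores <- score_pairs_vec(matrices$vertex,
                              unname(vt[unname(M$vertices)]),
                              unname(qvt[names(M$vertices)]))
  e_scores <- if (length(M$edges)) {
    score_pairs_vec(matrices$edge,
                    unname(et[unname(M$edges)]),
                    unname(qet[names(M$edges)]))
  } else numeric(0)
  mean(c(v_scores, e_scores))
}

#' Threshold acceptance for a set of element scores
#'
#' Two modes are supported.  `per_element`: every element of the match must
#' score at or above the threshold.  `cumulative`: the elements must
#' cumulatively reach the threshold, i.e. their mean (the SS) must.
#' Comparisons use `>=` (a match at a level equal to, or above, the
#' threshold is accepted).
#'
#' @param element_scores numeric vector of scores in \[-1, 1\]
#' @param st semantic threshold in \[0, 1\]
#' @param mode `"per_element"` or `"cumulative"`
#' @return logical flag
#' @export
passes_threshold <- function(element_scores, st, mode = c("per_element", "cumulative")) {
  mode <- match.arg(mode)
  if (length(element_scores) == 0) return(TRUE)
  if (mode == "per_element") all(element_scores >= st - 1e-12)
  else mean(element_scores) >= st - 1e-12
}

#' Search configuration
#'
#' Bundles the knobs of a mining run.  `st` is the semantic threshold in
#' \[0, 1\]; `mode` selects per-element or cumulative thresholding;
#' `anchor_type` is the vertex type the initial candidate set is drawn from
#' (Compound in the drug-repositioning setting); `prune` and `split` toggle
#' semantic graph pruning and query splitting (`NULL` picks the defaults:
#' pruning on in per-element mode, off in cumulative mode, where pruning can
#' discard below-threshold elements that a high-scoring mapping could have
#' absorbed; splitting on for queries with 4+ vertices).
#'
#' @param st semantic threshold in \[0, 1\]
#' @param mode `"per_element"` or `"cumulative"`
#' @param anchor_type vertex type of the initial candidate set
#' @param prune logical or `NULL` (auto)
#' @param split logical or `NULL` (auto)
#' @param seed integer seed for any randomised step
#' @param max_mappings optional cap on returned mappings (`Inf` = none)
#' @param dedup_orbits collapse automorphic re-embeddings onto the same
#'   target elements (off by default; raw-count semantics)
#' @param strict_degree optional strict closed-world variant that additionally
#'   requires total-degree equality between each mapped target vertex and its
#'   query role
#' @return an object of class `search_config`
#' @export
search_config <- function(st = 0.8, mode = c("per_element", "cumulative"),
                          anchor_type = "Compound", prune = NULL, split = NULL,
                          seed = 1L, max_mappings = Inf, dedup_orbits = FALSE,
                          strict_degree = FALSE) {
  mode <- match.arg(mode)
  if (!is.numeric(st) || length(st) != 1 || is.na(st) || st < 0 || st > 1) {
    stop("st must be a single number in [0, 1]", call. = FALSE)
  }
  if (is.null(prune)) prune <- (mode == "per_element")
  structure(
    list(st = st, mode = mode, anchor_type = anchor_type,
         prune = isTRUE(prune), split = if (is.null(split)) NA else isTRUE(split),
         seed = as.integer(seed), max_mappings = max_mappings,
         dedup_orbits = isTRUE(dedup_orbits), strict_degree = isTRUE(strict_degree)),
    class = "search_config"
  )
}
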