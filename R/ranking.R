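#' Score a query by its recovery of known interactions
#'
#' A query's score \eqn{R_q} is the fraction of its *unique* inferred
#' drug-target pairs that are known: the inferred pairs are deduplicated to
#' a set first, then \eqn{R_q = |unique \cap reference| / |unique|}.  A query
#' with no inferences scores 0.
#'
#' @param inferred data frame with columns `drug`, `target` (one row per
#'   mapping; duplicates allowed)
#' @param reference a `reference_set` from [relevant_interactions()], or a
#'   data frame with columns `drug`, `target`
#' @param query_id optional identifier carried through to the result
#' @return an object of class `query_score`: list with `query_id`, `rq`,
#'   `inferred_unique` (data frame) and `n_known`
#' @export
score_query <- function(inferred, reference, query_id = NA_character_) {
  ref <- if (inherits(reference, "reference_set")) reference$pairs else
    as.data.frame(reference, stringsAsFactors = FALSE)
  inf <- as.data.frame(inferred, stringsAsFactors = FALSE)
  if (nrow(inf) > 0) {
    inf <- inf[!duplicated(paste(inf$drug, inf$target)), c("drug", "target"), drop = FALSE]
    rownames(inf) <- NULL
  } else {
    inf <- data.frame(drug = character(0), target = character(0))
  }
  n_known <- if (nrow(inf) == 0) 0L else
    sum(paste(inf$drug, inf$target) %in% paste(ref$drug, ref$target))
  rq <- if (nrow(inf) == 0) 0 else n_known / nrow(inf)
  structure(
    list(query_id = query_id, rq = rq, inferred_unique = inf,
         n_known = as.integer(n_known)),
    class = "query_score"
  )
}

#' @export
print.query_score <- function(x, ...) {
  cat(sprintf("query_score %s: rq = %.5f (%d known / %d unique inferred)\n",
              x$query_id, x$rq, x$n_known, nrow(x$inferred_unique)))
  invisible(x)
}

#' Cumulative interaction scores over all supporting queries
#'
#' Each distinct inferred pair receives \eqn{R_i = \sum R_q} over the
#' queries whose unique inferred set contains it (a pair inferred several
#' times by one query counts that query once).  Pairs inferred by no scored
#' query are absent from the output.
#'
#' @param per_query_inferences named list: query id -> data frame of inferred
#'   pairs (`drug`, `target`)
#' @param scores list of `query_score` objects covering every query id
#'   present (see [score_query()])
#' @return data frame with columns `drug`, `target`, `ri`,
#'   `n_supporting_queries`, `supporting_query_ids` (comma-separated)
#' @export
score_interactions <- function(per_query_inferences, scores) {
  score_ids <- vapply(scores, function(s) s$query_id, character(1))
  rq <- stats::setNames(vapply(scores, function(s) s$rq, numeric(1)), score_ids)
  missing <- setdiff(names(per_query_inferences), score_ids)
  if (length(missing) > 0) {
    stop("no score for query id: ", missing[1], call. = FALSE)
  }
  acc <- new.env(parent = emptyenv())
  for (qid in names(per_query_inferences)) {
    inf <- per_query_inferences[[qid]]
    if (nrow(inf) == 0) next
    keys <- unique(paste(inf$drug, inf$target, sep = "\r"))
    for (kk in keys) {
      cur <- if (exists(kk, envir = acc, inherits = FALSE)) {
        get(kk, envir = acc, inherits = FALSE)
      } else list(ri = 0, q = character(0))
      cur$ri <- cur$ri + rq[[qid]]
      cur$q <- c(cur$q, qid)
      assign(kk, cur, envir = acc)
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0) {
    return(data.frame(drug = character(0), target = character(0),
                      ri = numeric(0), n_supporting_queries = integer(0),
                      supporting_query_ids = character(0)))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  entries <- lapply(keys, function(kk) get(kk, envir = acc, inherits = FALSE))
  data.frame(
    drug = vapply(parts, `[`, character(1), 1),
    target = vapply(parts, `[`, character(1), 2),
    ri = vapply(entries, function(e) e$ri, numeric(1)),
    n_supporting_queries = vapply(entries, function(e) length(e$q), integer(1)),
    supporting_query_ids = vapply(entries, function(e)
      paste(sort(e$q), collapse = ","), character(1))
  )
}

#' Rank inferred interactions by cumulative score
#'
#' Orders interactions by descending \eqn{R_i}; ties are broken by
#' descending number of supporting queries, then drug id, then target id
#' (a deterministic artifact of this implementation; higher-ranked
#' interactions are inferred with greater confidence).
#'
#' @param interactions data frame from [score_interactions()]
#' @return the same frame ordered, with a leading `rank` column
#' @export
rank_interactions <- function(interactions) {
  if (nrow(interactions) == 0) {
    return(cbind(rank = integer(0), interactions))
  }
  ord <- order(-interactions$ri, -interactions$n_supporting_queries,
               interactions$drug, interactions$target)
  out <- interactions[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Score and rank inferred interactions against a reference set
#'
#' Convenience pipeline over [score_query()], [score_interactions()] and
#' [rank_interactions()].  Interactions already present as interaction-type
#' edges in `G` are excluded from the output (the closed-world rule already
#' prevents them; the filter is belt-and-braces).
#'
#' @param per_query_inferences named list: query id -> data frame (`drug`,
#'   `target`)
#' @param reference a `reference_set` or data frame (`drug`, `target`)
#' @param G optional [typed_graph()] used for the existing-edge exclusion
#' @param interaction_edge_type edge type used for the exclusion
#' @return ranked data frame as [rank_interactions()]
#' @export
rank_inferred_interactions <- function(per_query_inferences, reference,
                                       G = NULL,
                                       interaction_edge_type = "binds_to") {
  scores <- lapply(names(per_query_inferences), function(qid) {
    score_query(per_query_inferences[[qid]], reference, query_id = qid)
  })
  tab <- score_interactions(per_query_inferences, scores)
  if (!is.null(G) && nrow(tab) > 0) {
    e <- G$edges[G$edges$type == interaction_edge_type, , drop = FALSE]
    linked <- c(paste(e$source, e$target), paste(e$target, e$source))
    tab <- tab[!(paste(tab$drug, tab$target) %in% linked), , drop = FALSE]
  }
  rank_interactions(tab)
}
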