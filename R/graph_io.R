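#' Read a typed graph from GraphML or TSV
#'
#' Two on-disk dialects are supported.  GraphML: a directed graph whose nodes
#' and edges each carry a `data` entry for a key with `attr.name = "type"`
#' (mandatory); every other data key becomes an attribute.  TSV: `path` is a
#' directory containing `nodes.tsv` (columns `id`, `type`, `attrs`) and
#' `edges.tsv` (columns `id`, `source`, `target`, `type`, `attrs`), with
#' attributes serialised `key=value;key=value`.
#'
#' @param path file (GraphML) or directory (TSV)
#' @param format `"graphml"` or `"tsv"`
#' @return a [typed_graph()]
#' @seealso [save_graph()]
#' @export
load_graph <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such path: ", path, call. = FALSE)
  if (format == "graphml") load_graphml(path) else load_graph_tsv(path)
}

#' Write a typed graph to GraphML or TSV
#'
#' The written file(s) reload to an equal graph: same vertex set, edge
#' multiset, types and attributes.
#'
#' @param G a [typed_graph()]
#' @param path file (GraphML) or directory (TSV; created if absent)
#' @param format `"graphml"` or `"tsv"`
#' @return invisibly, `path`
#' @export
save_graph <- function(G, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  validate_typed_graph(G)
  if (format == "graphml") save_graphml(G, path) else save_graph_tsv(G, path)
  invisible(path)
}

## ---- GraphML ----

load_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_for <- xml2::xml_attr(keys, "for")
  key_name <- xml2::xml_attr(keys, "attr.name")
  key_id <- xml2::xml_attr(keys, "id")
  key_map <- data.frame(id = key_id, for_ = key_for, name = key_name)

  read_elements <- function(xpath, what, id_default_prefix) {
    nodes <- xml2::xml_find_all(doc, xpath)
    n <- length(nodes)
    ids <- xml2::xml_attr(nodes, "id")
    auto <- paste0(id_default_prefix, seq_len(n))
    ids[is.na(ids)] <- auto[is.na(ids)]
    types <- character(n)
    attrs <- vector("list", n)
    for (i in seq_len(n)) {
      data_nodes <- xml2::xml_find_all(nodes[[i]], "./data")
      dkeys <- xml2::xml_attr(data_nodes, "key")
      dvals <- xml2::xml_text(data_nodes)
      dnames <- key_map$name[match(dkeys, key_map$id)]
      dnames[is.na(dnames)] <- dkeys[is.na(dnames)]
      is_type <- dnames == "type"
      if (!any(is_type)) {
        stop(sprintf("GraphML %s '%s' lacks the mandatory 'type' data key",
                     what, ids[i]), call. = FALSE)
      }
      types[i] <- dvals[which(is_type)[1]]
      attrs[[i]] <- stats::setNames(dvals[!is_type], dnames[!is_type])
    }
    list(ids = ids, types = types, attrs = attrs, nodes = nodes)
  }

  nd <- read_elements(".//graph/node", "node", "n")
  ed <- read_elements(".//graph/edge", "edge", "e")
  e_src <- vapply(ed$nodes, function(x) xml2::xml_attr(x, "source"), character(1))
  e_tgt <- vapply(ed$nodes, function(x) xml2::xml_attr(x, "target"), character(1))

  vertices <- data.frame(id = nd$ids, type = nd$types)
  vertices$attrs <- nd$attrs
  edges <- data.frame(
    id = ed$ids, source = e_src, target = e_tgt,
    type = if (length(ed$ids)) ed$types else character(0)
  )
  edges$attrs <- ed$attrs
  typed_graph(vertices, edges)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

save_graphml <- function(G, path) {
  # Assemble the document as text: xml2 node-by-node construction is slow for
  # graphs with 1e4+ elements, and the GraphML we emit is structurally simple.
  v_attr_names <- sort(unique(unlist(lapply(G$vertices$attrs, names))))
  e_attr_names <- sort(unique(unlist(lapply(G$edges$attrs, names))))
  key_defs <- c(
    "<key id=\"vtype\" for=\"node\" attr.name=\"type\" attr.type=\"string\"/>",
    "<key id=\"etype\" for=\"edge\" attr.name=\"type\" attr.type=\"string\"/>",
    sprintf("<key id=\"va%d\" for=\"node\" attr.name=\"%s\" attr.type=\"string\"/>",
            seq_along(v_attr_names), xml_escape(v_attr_names)),
    sprintf("<key id=\"ea%d\" for=\"edge\" attr.name=\"%s\" attr.type=\"string\"/>",
            seq_along(e_attr_names), xml_escape(e_attr_names))
  )
  v_key_id <- stats::setNames(sprintf("va%d", seq_along(v_attr_names)), v_attr_names)
  e_key_id <- stats::setNames(sprintf("ea%d", seq_along(e_attr_names)), e_attr_names)

  attr_data <- function(attrs, key_ids) {
    if (length(attrs) == 0) return("")
    paste0(sprintf("<data key=\"%s\">%s</data>",
                   key_ids[names(attrs)], xml_escape(unname(attrs))),
           collapse = "")
  }
  v_lines <- vapply(seq_len(nrow(G$vertices)), function(i) {
    sprintf("<node id=\"%s\"><data key=\"vtype\">%s</data>%s</node>",
            xml_escape(G$vertices$id[i]), xml_escape(G$vertices$type[i]),
            attr_data(G$vertices$attrs[[i]], v_key_id))
  }, character(1))
  e_lines <- vapply(seq_len(nrow(G$edges)), function(i) {
    sprintf("<edge id=\"%s\" source=\"%s\" target=\"%s\"><data key=\"etype\">%s</data>%s</edge>",
            xml_escape(G$edges$id[i]), xml_escape(G$edges$source[i]),
            xml_escape(G$edges$target[i]), xml_escape(G$edges$type[i]),
            attr_data(G$edges$attrs[[i]], e_key_id))
  }, character(1))

  txt <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    key_defs,
    "<graph edgedefault=\"directed\">",
    v_lines, e_lines,
    "</graph>", "</graphml>"
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(txt, con)
}

## ---- TSV ----

attr_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  gsub("\n", "%0A", x, fixed = TRUE)
}

attr_decode <- function(x) {
  x <- gsub("%0A", "\n", x, fixed = TRUE)
  x <- gsub("%09", "\t", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

serialise_attrs <- function(attrs) {
  vapply(attrs, function(a) {
    if (length(a) == 0) return("")
    paste0(attr_encode(names(a)), "=", attr_encode(unname(a)), collapse = ";")
  }, character(1))
}

deserialise_attrs <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    stats::setNames(
      vapply(kv, function(p) attr_decode(p[2]), character(1)),
      vapply(kv, function(p) attr_decode(p[1]), character(1))
    )
  })
}

load_graph_tsv <- function(path) {
  npath <- file.path(path, "nodes.tsv")
  epath <- file.path(path, "edges.tsv")
  for (p in c(npath, epath)) {
    if (!file.exists(p)) stop("TSV graph directory lacks ", basename(p), call. = FALSE)
  }
  nd <- utils::read.delim(npath, colClasses = "character")
  ed <- utils::read.delim(epath, colClasses = "character")
  vertices <- data.frame(id = nd$id, type = nd$type)
  vertices$attrs <- deserialise_attrs(if (is.null(nd$attrs)) rep("", nrow(nd)) else nd$attrs)
  edges <- data.frame(id = ed$id, source = ed$source, target = ed$target, type = ed$type)
  edges$attrs <- deserialise_attrs(if (is.null(ed$attrs)) rep("", nrow(ed)) else ed$attrs)
  typed_graph(vertices, edges)
}

save_graph_tsv <- function(G, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  nd <- data.frame(
    id = G$vertices$id, type = G$vertices$type,
    attrs = serialise_attrs(G$vertices$attrs)
  )
  ed <- data.frame(
    id = G$edges$id, source = G$edges$source, target = G$edges$target,
    type = G$edges$type, attrs = serialise_attrs(G$edges$attrs)
  )
  utils::write.table(nd, file.path(path, "nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ed, file.path(path, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
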