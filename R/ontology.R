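#' Build an ontology DAG with propagated gene annotations
#'
#' Terms are related by `is_a` edges (child to parent) forming a DAG; a
#' gene annotated to a term is implicitly annotated to all of that term's
#' ancestors, and [ontology()] materialises that propagation.
#'
#' @param terms data.frame with columns `term`, `name` and optionally
#'   `namespace` (defaults to `"default"`); one row per term.
#' @param edges data.frame with columns `child`, `parent` (is_a edges).
#' @param annotations data.frame with columns `gene`, `term` (direct
#'   annotations).
#' @return object of class `ontology`: list with `terms`, `edges`,
#'   `parents`/`children` adjacency lists, `direct` and `genes`
#'   (propagated) term-to-gene lists.
#' @export
ontology <- function(terms, edges, annotations) {
  if (is.null(terms$namespace)) terms$namespace <- "default"
  terms$term <- as.character(terms$term)
  ids <- terms$term
  if (anyDuplicated(ids)) stop("duplicate term ids")
  bad <- setdiff(unique(c(edges$child, edges$parent)), ids)
  if (length(bad)) stop("edge references unknown term(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(annotations$term), ids)
  if (length(bad)) stop("annotation references unknown term(s): ",
                        paste(bad, collapse = ", "))
  parents <- lapply(setNames(ids, ids), function(t)
    unique(as.character(edges$parent[edges$child == t])))
  children <- lapply(setNames(ids, ids), function(t)
    unique(as.character(edges$child[edges$parent == t])))
  # acyclicity check via Kahn's algorithm
  indeg <- vapply(parents, length, integer(1))
  queue <- ids[indeg == 0]
  seen <- 0L
  indeg_work <- indeg
  while (length(queue)) {
    t <- queue[1]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg_work[ch] <- indeg_work[ch] - 1L
      if (indeg_work[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(ids)) stop("ontology edges contain a cycle")
  direct <- lapply(setNames(ids, ids), function(t)
    unique(as.character(annotations$gene[annotations$term == t])))
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(t) {
    if (!is.null(anc_cache[[t]])) return(anc_cache[[t]])
    out <- character(0)
    for (p in parents[[t]]) out <- union(out, c(p, ancestors(p)))
    anc_cache[[t]] <- out
    out
  }
  genes <- direct
  for (t in ids) {
    if (!length(direct[[t]])) next
    for (a in ancestors(t)) genes[[a]] <- union(genes[[a]], direct[[t]])
  }
  structure(list(terms = terms, edges = edges, parents = parents,
                 children = children, direct = direct, genes = genes),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("Ontology: %d terms, %d is_a edges, %d propagated annotations\n",
              nrow(x$terms), nrow(x$edges),
              sum(lengths(x$genes))))
  invisible(x)
}

#' Read an ontology from OBO or TSV files
#'
#' `read_obo()` parses a minimal OBO subset (`[Term]` stanzas with `id`,
#' `name`, `namespace` and `is_a` tags). `read_ontology_tsv()` takes
#' 2-column TSV edge (`child`, `parent`) and annotation (`gene`, `term`)
#' files, with an optional term table (`term`, `name`, `namespace`).
#'
#' @param path OBO file.
#' @param annotations data.frame or 2-column TSV path of gene-to-term
#'   annotations.
#' @return an [ontology] object.
#' @export
read_obo <- function(path, annotations) {
  lines <- readLines(path)
  terms <- list()
  edges <- list()
  cur <- NULL
  for (ln in c(lines, "[Term]")) {
    if (grepl("^\\[", ln)) {
      if (!is.null(cur) && !is.null(cur$id)) {
        terms[[length(terms) + 1L]] <- data.frame(
          term = cur$id, name = cur$name %||% cur$id,
          namespace = cur$namespace %||% "default", stringsAsFactors = FALSE)
        for (p in cur$is_a) {
          edges[[length(edges) + 1L]] <- data.frame(
            child = cur$id, parent = p, stringsAsFactors = FALSE)
        }
      }
      cur <- if (ln == "[Term]") list(is_a = character()) else NULL
    } else if (!is.null(cur)) {
      if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
      if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
      if (startsWith(ln, "namespace:")) {
        cur$namespace <- trimws(sub("^namespace:", "", ln))
      }
      if (startsWith(ln, "is_a:")) {
        cur$is_a <- c(cur$is_a,
                      trimws(sub("!.*$", "", sub("^is_a:", "", ln))))
      }
    }
  }
  if (is.character(annotations)) {
    annotations <- read.table(annotations, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }
  ontology(do.call(rbind, terms),
           if (length(edges)) do.call(rbind, edges)
           else data.frame(child = character(), parent = character()),
           annotations)
}

#' @rdname read_obo
#' @param edges_path 2-column TSV (`child`, `parent`).
#' @param annotations_path 2-column TSV (`gene`, `term`).
#' @param terms_path optional TSV (`term`, `name`, `namespace`).
#' @export
read_ontology_tsv <- function(edges_path, annotations_path, terms_path = NULL) {
  edges <- read.table(edges_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  annotations <- read.table(annotations_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!is.null(terms_path)) {
    terms <- read.table(terms_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  } else {
    ids <- unique(c(edges$child, edges$parent, annotations$term))
    terms <- data.frame(term = ids, name = ids, namespace = "default",
                        stringsAsFactors = FALSE)
  }
  ontology(terms, edges, annotations)
}

#' Related-term group: an ancestor and all its descendants
#'
#' @param ont an [ontology].
#' @param ancestor term id.
#' @return character vector of term ids (the ancestor plus every term
#'   reachable from it along reversed is_a edges; diamonds counted once).
#' @export
related_term_group <- function(ont, ancestor) {
  if (!ancestor %in% ont$terms$term) stop("unknown term: ", ancestor)
  out <- character(0)
  stack <- ancestor
  while (length(stack)) {
    t <- stack[[1]]
    stack <- stack[-1]
    if (t %in% out) next
    out <- c(out, t)
    stack <- c(stack, ont$children[[t]])
  }
  sort(out)
}
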