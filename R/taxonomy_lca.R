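TAXONOMIC_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
                     "genus", "species")

#' Construct a rooted taxonomy tree
#'
#' @param nodes data.frame with columns `id`, `parent`, `name`, `rank`. The
#'   root is the single node whose parent equals its own id or is NA. Ranks
#'   are the seven canonical ranks plus `"no rank"`.
#' @return object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(all(c("id", "parent", "name", "rank") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  nodes$parent <- as.character(nodes$parent)
  if (anyDuplicated(nodes$id)) stop("duplicate taxon ids")
  is_root <- is.na(nodes$parent) | nodes$parent == nodes$id
  if (sum(is_root) != 1L) stop("taxonomy must have exactly one root")
  if (!all(nodes$parent[!is_root] %in% nodes$id)) {
    stop("some nodes reference a missing parent")
  }
  bad <- setdiff(unique(nodes$rank), c(TAXONOMIC_RANKS, "no rank"))
  if (length(bad)) stop("unknown rank(s): ", paste(bad, collapse = ", "))
  parent <- stats::setNames(nodes$parent, nodes$id)
  root <- nodes$id[is_root]
  parent[root] <- NA_character_
  # depth by walking up; also detects cycles
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$id)
  for (id in nodes$id) {
    path <- character(0)
    cur <- id
    while (is.na(depth[cur])) {
      if (cur %in% path) stop("taxonomy contains a cycle at node ", cur)
      path <- c(path, cur)
      p <- parent[cur]
      if (is.na(p)) { depth[cur] <- 0L; break }
      if (!is.na(depth[p])) { depth[cur] <- depth[p] + 1L; break }
      cur <- p
    }
    # fill the walked path downward
    while (length(path)) {
      last <- path[length(path)]
      if (is.na(depth[last])) depth[last] <- depth[parent[last]] + 1L
      path <- path[-length(path)]
    }
  }
  structure(list(parent = parent, root = root,
                 name = stats::setNames(nodes$name, nodes$id),
                 rank = stats::setNames(nodes$rank, nodes$id),
                 depth = depth),
            class = "taxonomy_tree")
}

#' Read a taxonomy from NCBI-dump-like TSV files
#'
#' `nodes_file` has columns `id`, `parent`, `rank`; `names_file` has `id`,
#' `name`. Both are tab-separated with a header row.
#'
#' @param nodes_file,names_file file paths.
#' @return a [taxonomy_tree()].
#' @export
read_taxonomy_tsv <- function(nodes_file, names_file) {
  nd <- utils::read.delim(nodes_file, stringsAsFactors = FALSE,
                          colClasses = "character")
  nm <- utils::read.delim(names_file, stringsAsFactors = FALSE,
                          colClasses = "character")
  nd$name <- nm$name[match(nd$id, nm$id)]
  taxonomy_tree(nd)
}

# Path from a node up to the root, node first.
ancestor_path <- function(tree, id) {
  if (!id %in% names(tree$parent)) stop("unknown taxon id: ", id)
  path <- id
  while (!is.na(tree$parent[id])) {
    id <- tree$parent[[id]]
    path <- c(path, id)
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tree a [taxonomy_tree()].
#' @param taxa non-empty character vector of taxon ids.
#' @return the id of the deepest node ancestral to (or equal to) every
#'   input taxon.
#' @export
lca <- function(tree, taxa) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("taxon set must be non-empty")
  common <- ancestor_path(tree, taxa[1])
  for (t in taxa[-1]) common <- intersect(common, ancestor_path(tree, t))
  common[which.max(tree$depth[common])]
}

#' Full lineage of a taxon
#'
#' @param tree a [taxonomy_tree()].
#' @param id taxon id.
#' @return named character vector of taxon *names* at each canonical rank
#'   on the root-to-node path (NA where the path has no node of that rank),
#'   with attribute `node` holding the assigned node id.
#' @export
lineage <- function(tree, id) {
  path <- rev(ancestor_path(tree, id))
  out <- stats::setNames(rep(NA_character_, length(TAXONOMIC_RANKS)),
                         TAXONOMIC_RANKS)
  for (n in path) {
    r <- tree$rank[[n]]
    if (r %in% TAXONOMIC_RANKS) out[r] <- tree$name[[n]]
  }
  attr(out, "node") <- id
  out
}

# A second-stage query: the matched subject region of the best first-stage
# hit, used to seed the second homology search.
subject_region <- function(subject, begin, end) {
  structure(list(subject = subject, begin = begin, end = end),
            class = "subject_region")
}

validate_hits <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(subject = character(0), evalue = numeric(0),
                      pident = numeric(0), sstart = numeric(0),
                      send = numeric(0)))
  }
  stopifnot(all(c("subject", "evalue") %in% names(hits)))
  if (any(hits$evalue <= 0)) stop("e-values must be positive")
  # deterministic order: ascending e-value, subject id breaking ties
  hits[order(hits$evalue, hits$subject), , drop = FALSE]
}

#' Annotate a gene by dual-search lowest common ancestor
#'
#' Runs the homology search for the query; if the best e-value exceeds
#' `e_threshold` the result is `"no hit"`. Otherwise the best hit's matched
#' subject region seeds a second search, and every second-search hit whose
#' e-value is at most the first search's best e-value forms the homolog
#' neighborhood. The gene is assigned the lowest common ancestor of the
#' neighborhood's taxa (the seed subject is part of its own neighborhood).
#'
#' @param query the gene query, passed through to the backend.
#' @param backend a function taking either the original query or a
#'   [subject_region()] and returning a data.frame of hits with columns
#'   `subject`, `evalue`, `pident`, `sstart`, `send`; deterministic for
#'   fixed inputs.
#' @param tree a [taxonomy_tree()].
#' @param subject_taxa named character vector mapping subject ids to taxon
#'   ids; subjects without a mapping are skipped with a warning.
#' @param e_threshold e-value above which the first search is a no-hit.
#' @return a [lineage()] of the assigned node, or `NULL` (no hit).
#' @export
annotate_gene <- function(query, backend, tree, subject_taxa,
                          e_threshold = 1e-5) {
  h1 <- validate_hits(backend(query))
  if (nrow(h1) == 0L || min(h1$evalue) > e_threshold) return(NULL)
  best <- h1[1L, ]
  h2 <- validate_hits(backend(subject_region(best$subject, best$sstart,
                                             best$send)))
  nb <- h2[h2$evalue <= best$evalue, , drop = FALSE]
  if (!best$subject %in% nb$subject) nb <- rbind(best, nb)
  known <- nb$subject %in% names(subject_taxa)
  if (any(!known)) {
    warning("skipping hit(s) without taxon mapping: ",
            paste(unique(nb$subject[!known]), collapse = ", "))
  }
  taxa <- unique(subject_taxa[nb$subject[known]])
  if (length(taxa) == 0L) return(NULL)
  lineage(tree, lca(tree, taxa))
}

#' Read a tabular homology hit table
#'
#' Expects BLAST-style tab-separated columns `qseqid`, `sseqid`, `pident`,
#' `evalue`, `sstart`, `send` with a header row.
#'
#' @param path file path.
#' @return data.frame with one row per hit.
#' @export
read_hits_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("qseqid", "sseqid", "pident", "evalue", "sstart", "send")
                %in% names(df)))
  df
}

#' Turn a hit table into a deterministic search backend
#'
#' Builds a [annotate_gene()] backend from a precomputed hit table: query
#' ids are looked up in `qseqid`; [subject_region()] queries are looked up
#' in `region_qseqid` (an id of the form `subject:begin-end`).
#'
#' @param hits a data.frame as returned by [read_hits_tsv()].
#' @return backend function.
#' @export
table_backend <- function(hits) {
  function(query) {
    key <- if (inherits(query, "subject_region")) {
      sprintf("%s:%d-%d", query$subject, query$begin, query$end)
    } else {
      as.character(query)
    }
    h <- hits[hits$qseqid == key, , drop = FALSE]
    data.frame(subject = h$sseqid, evalue = h$evalue, pident = h$pident,
               sstart = h$sstart, send = h$send, stringsAsFactors = FALSE)
  }
}
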