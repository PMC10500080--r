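# NCBI-style taxonomy: load the taxdump flat files, answer lineage and
# subtree-membership queries, and locate each organism's closest
# reference ancestor.

read_dmp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t")
}

#' Load an NCBI taxonomy from taxdump flat files
#'
#' @param nodes_path `nodes.dmp` (taxid, parent taxid, rank, ...).
#' @param names_path `names.dmp` (taxid, name, unique name, name class);
#'   scientific names (class `"scientific name"`) are attached to nodes.
#' @param merged_path Optional `merged.dmp` (old id, new id); merged ids
#'   are transparently redirected at every query entry point.
#' @return A `taxonomy_tree`: `parent` (named integer, names = taxid),
#'   `rank`, `sci_name` (named character), `children` (named list),
#'   `merged` (named integer old -> new), `root` (taxid 1 by NCBI
#'   convention: the root is its own parent).
#' @export
load_taxonomy <- function(nodes_path, names_path, merged_path = NULL) {
  nd <- read_dmp(nodes_path)
  taxid <- vapply(nd, function(x) as.integer(x[1L]), integer(1))
  parent <- vapply(nd, function(x) as.integer(x[2L]), integer(1))
  rank <- vapply(nd, function(x) if (length(x) >= 3L) x[3L] else "",
                 character(1))
  if (anyDuplicated(taxid)) {
    stop("integrity error: duplicated taxids in nodes.dmp: ",
         paste(unique(taxid[duplicated(taxid)]), collapse = ", "))
  }
  key <- as.character(taxid)
  parent <- stats::setNames(parent, key)
  rank <- stats::setNames(rank, key)

  orphans <- taxid[!(parent %in% taxid)]
  # NCBI root (1) is its own parent; anything else unreachable is an orphan
  orphans <- setdiff(orphans, taxid[parent == taxid])
  if (length(orphans)) {
    stop("integrity error: orphan taxids (parent absent): ",
         paste(orphans, collapse = ", "))
  }
  roots <- taxid[parent == taxid]
  if (length(roots) != 1L) {
    stop("integrity error: expected exactly one root, found: ",
         paste(roots, collapse = ", "))
  }

  nm <- read_dmp(names_path)
  nm_tax <- vapply(nm, function(x) x[1L], character(1))
  nm_name <- vapply(nm, function(x) x[2L], character(1))
  nm_class <- vapply(nm, function(x) if (length(x) >= 4L) x[4L] else "",
                     character(1))
  sci <- nm_name[nm_class == "scientific name"]
  sci_tax <- nm_tax[nm_class == "scientific name"]
  sci_name <- stats::setNames(rep(NA_character_, length(taxid)), key)
  sci_name[sci_tax[sci_tax %in% key]] <- sci[sci_tax %in% key]
  missing_sci <- key[is.na(sci_name)]
  if (length(missing_sci)) {
    warning(length(missing_sci),
            " node(s) without a scientific name (left empty): ",
            paste(utils::head(missing_sci, 5L), collapse = ", "))
    sci_name[missing_sci] <- ""
  }

  merged <- integer()
  if (!is.null(merged_path) && file.exists(merged_path)) {
    mg <- read_dmp(merged_path)
    old <- vapply(mg, function(x) x[1L], character(1))
    new <- vapply(mg, function(x) as.integer(x[2L]), integer(1))
    keep <- !(old %in% key)  # merged ids never appear as nodes
    merged <- stats::setNames(new[keep], old[keep])
  }

  children <- stats::setNames(vector("list", length(taxid)), key)
  for (i in seq_along(taxid)) {
    if (parent[i] != taxid[i]) {
      pk <- as.character(parent[i])
      children[[pk]] <- c(children[[pk]], taxid[i])
    }
  }

  structure(list(
    taxids = taxid, parent = parent, rank = rank, sci_name = sci_name,
    children = children, merged = merged, root = roots,
    cache = new.env(parent = emptyenv())
  ), class = "taxonomy_tree")
}

#' Resolve a taxid through merged-id redirects
#'
#' @param t A `taxonomy_tree`.
#' @param taxid Integer taxid(s).
#' @return Current taxid(s); `NA` where unknown (deleted ids count as
#'   unknown).
#' @export
resolve_taxid <- function(t, taxid) {
  taxid <- as.integer(taxid)
  key <- as.character(taxid)
  out <- ifelse(key %in% names(t$parent), taxid,
                unname(t$merged[key]))
  as.integer(out)
}

tax_key <- function(t, taxid, what = "taxid") {
  r <- resolve_taxid(t, taxid)
  if (is.na(r)) stop("unknown ", what, ": ", taxid)
  as.character(r)
}

#' Lineage of a taxon
#'
#' @param t A `taxonomy_tree`.
#' @param taxid Taxid (merged ids redirected).
#' @return Integer vector from the taxon itself up to the root,
#'   inclusive, nearest-first.
#' @export
tax_lineage <- function(t, taxid) {
  key <- tax_key(t, taxid)
  hit <- t$cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- integer()
  cur <- as.integer(key)
  repeat {
    out <- c(out, cur)
    p <- t$parent[[as.character(cur)]]
    if (p == cur) break
    cur <- p
  }
  t$cache[[key]] <- out
  out
}

#' Subtree membership test
#'
#' True iff `ancestor` lies on `query`'s parent chain or equals it.
#'
#' @param t A `taxonomy_tree`.
#' @param query,ancestor Taxids (merged ids redirected).
#' @export
is_in_subtree <- function(t, query, ancestor) {
  a <- resolve_taxid(t, ancestor)
  if (is.na(a)) stop("unknown taxid: ", ancestor)
  a %in% tax_lineage(t, query)
}

#' Closest reference ancestor of a taxon
#'
#' Walks from the taxon toward the root and returns the first member of
#' `refset` encountered; the taxon itself is eligible.
#'
#' @param t A `taxonomy_tree`.
#' @param taxid Query taxid.
#' @param refset Integer vector of reference-node taxids.
#' @return A taxid, or `NA` if no reference node lies on the lineage.
#' @export
closest_reference_ancestor <- function(t, taxid, refset) {
  lin <- tax_lineage(t, taxid)
  hit <- lin[lin %in% as.integer(refset)]
  if (length(hit)) hit[1L] else NA_integer_
}

#' All taxa in a subtree
#'
#' @param t A `taxonomy_tree`.
#' @param taxid Subtree root (merged ids redirected).
#' @return Integer vector of taxids, the root of the subtree included.
#' @export
tax_subtree <- function(t, taxid) {
  key <- tax_key(t, taxid)
  out <- as.integer(key)
  frontier <- t$children[[key]]
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(t$children[as.character(frontier)],
                       use.names = FALSE)
  }
  out
}

#' Look up a taxon by scientific name
#'
#' @param t A `taxonomy_tree`.
#' @param name Scientific name (exact, case-insensitive).
#' @return The matching taxid; errors with nearest-name suggestions when
#'   absent.
#' @export
taxid_by_name <- function(t, name) {
  hit <- which(tolower(t$sci_name) == tolower(name))
  if (length(hit) == 0L) {
    sugg <- utils::head(
      t$sci_name[order(utils::adist(tolower(name),
                                    tolower(t$sci_name)))], 3L)
    stop("unknown taxon name '", name, "'; nearest matches: ",
         paste(sugg, collapse = ", "))
  }
  as.integer(names(t$sci_name)[hit[1L]])
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("<taxonomy_tree> ", length(x$taxids), " nodes, root ", x$root,
      ", ", length(x$merged), " merged redirects\n", sep = "")
  invisible(x)
}
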