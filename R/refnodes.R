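# Reference taxonomic nodes: selected from annotation quantity and
# diversity, or loaded verbatim from a published list.

#' Selection parameters for reference taxonomic nodes
#'
#' The concrete rule: a taxonomy node qualifies when its cumulative
#' annotation count (over its whole subtree) reaches
#' `min_annotations_unreliable` AND the number of distinct annotated
#' taxa below it reaches `min_species`; nodes additionally reaching
#' `min_annotations_reliable` are labelled `reliable`, the rest
#' `unreliable`. Candidates are restricted to ranks at or above species
#' (no strain-level reference nodes).
#'
#' @param min_annotations_unreliable Minimum cumulative annotations for
#'   selection at all (default 1000).
#' @param min_annotations_reliable Cumulative annotations needed for
#'   the `reliable` label (default 50000).
#' @param min_species Minimum distinct annotated taxa in the subtree
#'   (default 5).
#' @return A `selection_params` list.
#' @export
selection_params <- function(min_annotations_unreliable = 1000L,
                             min_annotations_reliable = 50000L,
                             min_species = 5L) {
  stopifnot(min_annotations_reliable >= min_annotations_unreliable)
  structure(list(
    min_annotations_unreliable = min_annotations_unreliable,
    min_annotations_reliable = min_annotations_reliable,
    min_species = min_species), class = "selection_params")
}

#' Select reference taxonomic nodes from a cleaned corpus
#'
#' Cumulative annotation and distinct-taxon counts are accumulated up
#' every annotated organism's lineage; nodes passing the thresholds in
#' `params` become reference nodes. Nested qualifying nodes are all
#' retained: organisms resolve to the deepest one through
#' [closest_reference_ancestor()].
#'
#' @param records Cleaned annotation data.frame.
#' @param t A `taxonomy_tree`.
#' @param params A [selection_params()].
#' @return A `reference_node_set`: data.frame `taxid`, `label`
#'   (`reliable`/`unreliable`), `n_annotations`, `n_species`.
#' @export
select_reference_nodes <- function(records, t,
                                   params = selection_params()) {
  if (nrow(records) == 0L) {
    warning("empty annotation stream: no reference nodes selected")
    return(empty_refnode_set())
  }
  per_taxon <- table(records$taxon_id)
  ann <- stats::setNames(integer(length(t$taxids)),
                         as.character(t$taxids))
  spp <- ann
  for (k in names(per_taxon)) {
    lin <- as.character(tax_lineage(t, as.integer(k)))
    ann[lin] <- ann[lin] + as.integer(per_taxon[[k]])
    spp[lin] <- spp[lin] + 1L
  }
  # rank restriction: nothing below species level
  below_species <- vapply(t$taxids, function(x) {
    lin <- tax_lineage(t, x)
    any(t$rank[as.character(lin[-1L])] == "species")
  }, logical(1))
  eligible <- t$taxids[!below_species]
  key <- as.character(eligible)
  sel <- eligible[ann[key] >= params$min_annotations_unreliable &
                    spp[key] >= params$min_species]
  if (length(sel) == 0L) return(empty_refnode_set())
  k <- as.character(sel)
  label <- ifelse(ann[k] >= params$min_annotations_reliable,
                  "reliable", "unreliable")
  structure(data.frame(taxid = sel, label = unname(label),
                       n_annotations = unname(ann[k]),
                       n_species = unname(spp[k])),
            class = c("reference_node_set", "data.frame"))
}

empty_refnode_set <- function() {
  structure(data.frame(taxid = integer(), label = character(),
                       n_annotations = integer(), n_species = integer()),
            class = c("reference_node_set", "data.frame"))
}

#' Load a reference-node list from TSV
#'
#' Lets users supply an externally published reference-node list
#' (columns `taxid`, `label`) instead of the automatic selection.
#' Labels are case-insensitive; counts are left zero.
#'
#' @param path TSV with header columns `taxid`, `label`.
#' @param t Optional `taxonomy_tree` for validating the taxids.
#' @return A `reference_node_set`.
#' @export
load_reference_nodes <- function(path, t = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxid", "label") %in% names(df))) {
    stop("reference-node file must have columns taxid, label: ", path)
  }
  if (anyDuplicated(df$taxid)) {
    stop("duplicate taxids in reference-node file: ",
         paste(unique(df$taxid[duplicated(df$taxid)]), collapse = ", "))
  }
  label <- tolower(df$label)
  if (!all(label %in% c("reliable", "unreliable"))) {
    stop("labels must be reliable/unreliable, got: ",
         paste(setdiff(unique(label), c("reliable", "unreliable")),
               collapse = ", "))
  }
  taxid <- as.integer(df$taxid)
  if (!is.null(t)) {
    resolved <- resolve_taxid(t, taxid)
    if (anyNA(resolved)) {
      stop("unknown taxids in reference-node file: ",
           paste(taxid[is.na(resolved)], collapse = ", "))
    }
    taxid <- resolved
  }
  structure(data.frame(taxid = taxid, label = label,
                       n_annotations = 0L, n_species = 0L),
            class = c("reference_node_set", "data.frame"))
}

#' Write a reference-node set as TSV
#'
#' @param refs A `reference_node_set`.
#' @param path Output path.
#' @export
write_reference_nodes <- function(refs, path) {
  utils::write.table(as.data.frame(refs)[, c("taxid", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
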