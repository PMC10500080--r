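# GAF 2.x annotation input and the corpus cleaning step.

#' Read a GAF 2.x annotation file
#'
#' Comment lines (leading `!`) are skipped; gzip input is transparent.
#' Malformed lines (fewer than 15 tab-separated columns) are dropped
#' with a count attached to the result. Multi-organism taxon fields
#' (`taxon:X|taxon:Y`) keep the first taxon, the annotated gene
#' product's organism by GAF convention.
#'
#' @param path GAF file, plain or gzip.
#' @param t Optional `taxonomy_tree`; when supplied, taxon ids are
#'   merged-redirected at read time (unknown ids kept verbatim and
#'   handled by [clean_annotations()]).
#' @return A data.frame of annotation records with columns `db`,
#'   `object_id`, `object_symbol`, `qualifiers`, `go_id`,
#'   `evidence_code`, `taxon_id`, `assigned_by`; attribute
#'   `n_malformed` counts skipped lines.
#' @export
read_gaf <- function(path, t = NULL) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 15L
  if (length(fields) && mean(ok) < 0.5) {
    stop("format error: >50% of lines lack mandatory GAF columns in ",
         path, " (wrong file?)")
  }
  n_malformed <- sum(!ok)
  fields <- fields[ok]
  col <- function(i) vapply(fields, `[[`, character(1), i)
  if (length(fields) == 0L) {
    out <- data.frame(db = character(), object_id = character(),
                      object_symbol = character(),
                      qualifiers = character(), go_id = character(),
                      evidence_code = character(), taxon_id = integer(),
                      assigned_by = character(), stringsAsFactors = FALSE)
    attr(out, "n_malformed") <- n_malformed
    return(out)
  }
  taxon_raw <- col(13L)
  first_taxon <- sub("\\|.*$", "", taxon_raw)
  taxon_id <- suppressWarnings(
    as.integer(sub("^taxon:", "", first_taxon)))
  if (!is.null(t)) {
    redirected <- resolve_taxid(t, taxon_id)
    taxon_id <- ifelse(is.na(redirected), taxon_id, redirected)
  }
  out <- data.frame(
    db = col(1L), object_id = col(2L), object_symbol = col(3L),
    qualifiers = col(4L), go_id = col(5L), evidence_code = col(7L),
    taxon_id = taxon_id, assigned_by = col(15L),
    stringsAsFactors = FALSE
  )
  attr(out, "n_malformed") <- n_malformed
  out
}

CLEANING_REASONS <- c("nd_evidence", "not_qualifier", "root_term",
                      "rnacentral", "environmental_sample",
                      "obsolete_term", "unknown_taxon")

#' Clean an annotation corpus
#'
#' Applies the corpus-cleaning rules, in order (a record removed for
#' multiple reasons is counted once, by the first matching rule):
#' \enumerate{
#'   \item `nd_evidence`: evidence code `ND` (no biological data);
#'   \item `not_qualifier`: a `NOT` qualifier (the protein does
#'     \emph{not} perform the function);
#'   \item `root_term`: annotation to a namespace root (GO:0005575,
#'     GO:0008150, GO:0003674);
#'   \item `rnacentral`: DB or assigned-by field `RNAcentral`;
#'   \item `environmental_sample`: the taxon's scientific name, or any
#'     ancestor's, contains "environmental sample" (case-insensitive);
#'   \item `obsolete_term`: GO id obsolete or absent from the ontology
#'     (alt_ids are first resolved to primary ids);
#'   \item `unknown_taxon`: taxid unresolvable after merged redirects.
#' }
#' Evidence codes other than ND are retained deliberately, IEA
#' included: electronically inferred annotations are the bulk of the
#' corpus and the constraint derivation relies on them.
#'
#' @param records Annotation data.frame from [read_gaf()].
#' @param g An `ontology_graph`.
#' @param t A `taxonomy_tree`.
#' @return The retained records (input order preserved, `go_id` and
#'   `taxon_id` rewritten to primary/current ids), with attribute
#'   `report`: a `cleaning_report` (named removal counts, `total_in`,
#'   `total_out`).
#' @export
clean_annotations <- function(records, g, t) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  mark <- function(cond, why) {
    reason[is.na(reason) & cond] <<- why
  }
  mark(records$evidence_code == "ND", "nd_evidence")
  quals <- strsplit(records$qualifiers, "|", fixed = TRUE)
  has_not <- vapply(quals, function(q) "NOT" %in% q, logical(1))
  mark(has_not, "not_qualifier")
  primary <- resolve_go_id(g, records$go_id)
  mark(!is.na(primary) & primary %in% unname(g$roots), "root_term")
  mark(records$db == "RNAcentral" | records$assigned_by == "RNAcentral",
       "rnacentral")

  resolved_tax <- resolve_taxid(t, records$taxon_id)
  env_tax <- env_sample_taxa(t, unique(resolved_tax[!is.na(resolved_tax)]))
  mark(!is.na(resolved_tax) & resolved_tax %in% env_tax,
       "environmental_sample")
  mark(is.na(primary) | g$obsolete[primary] %in% TRUE, "obsolete_term")
  mark(is.na(resolved_tax), "unknown_taxon")

  keep <- is.na(reason)
  out <- records[keep, , drop = FALSE]
  out$go_id <- primary[keep]
  out$taxon_id <- resolved_tax[keep]
  rownames(out) <- NULL

  counts <- vapply(CLEANING_REASONS,
                   function(r) sum(reason == r, na.rm = TRUE), integer(1))
  report <- structure(
    list(counts = counts, total_in = n, total_out = sum(keep)),
    class = "cleaning_report")
  attr(out, "report") <- report
  out
}

# Taxa whose lineage contains a scientific name matching
# "environmental sample" (case-insensitive).
env_sample_taxa <- function(t, taxids) {
  if (length(taxids) == 0L) return(integer())
  flagged <- as.integer(names(t$sci_name)[
    grepl("environmental sample", t$sci_name, ignore.case = TRUE)])
  if (length(flagged) == 0L) return(integer())
  taxids[vapply(taxids, function(x) {
    any(tax_lineage(t, x) %in% flagged)
  }, logical(1))]
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report> in:", x$total_in, " out:", x$total_out, "\n")
  for (r in names(x$counts)) {
    if (x$counts[[r]] > 0L) cat("  ", r, ": ", x$counts[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Serialize a cleaning report as two-column TSV
#'
#' @param report A `cleaning_report`.
#' @param path Output path.
#' @export
write_cleaning_report <- function(report, path) {
  df <- data.frame(
    reason = c(names(report$counts), "total_in", "total_out"),
    count = c(unname(report$counts), report$total_in, report$total_out))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
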