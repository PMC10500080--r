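# Cumulative GO term frequencies per reference node and the automatic
# "never_in" derivation, plus the constraint-set container and its
# on-demand expansion to the full prohibited set of any taxon.

#' Build a constraint set
#'
#' @param records data.frame with columns `taxon_id` (integer), `go_id`,
#'   `relation` (`never_in`/`only_in`/`allow`), `source`
#'   (`automatic`/`goc`/`manual`), `reference_node` (integer or NA) and
#'   optionally `scope` (`subtree`, the default, or `node`: the record
#'   applies to that exact taxon only, used by the only_in conversion's
#'   on-path ancestors).
#' @param meta Named list of provenance metadata (inputs, thresholds).
#' @return A `constraint_set`.
#' @export
constraint_set <- function(records = NULL, meta = list()) {
  if (is.null(records)) {
    records <- data.frame(taxon_id = integer(), go_id = character(),
                          relation = character(), source = character(),
                          reference_node = integer(),
                          scope = character(), stringsAsFactors = FALSE)
  }
  if (is.null(records$scope)) records$scope <- "subtree"
  if (is.null(records$reference_node)) records$reference_node <- NA_integer_
  stopifnot(all(records$relation %in% c("never_in", "only_in", "allow")),
            all(records$source %in% c("automatic", "goc", "manual")))
  bad <- records$source == "automatic" & records$relation != "never_in"
  if (any(bad)) stop("automatic records must be never_in")
  records <- unique(records[, c("taxon_id", "go_id", "relation",
                                "source", "reference_node", "scope")])
  rownames(records) <- NULL
  structure(list(records = records, meta = meta),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set> ", nrow(x$records), " records (",
      paste(names(table(x$records$source)),
            table(x$records$source), sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Group cleaned annotations by closest reference node
#'
#' @param records Cleaned annotation data.frame.
#' @param t A `taxonomy_tree`.
#' @param refs A `reference_node_set` (or integer vector of taxids).
#' @return Named list: one data.frame of annotation rows per reference
#'   node (names = taxids), plus a `.discard` element for records whose
#'   organism has no reference ancestor.
#' @export
group_by_reference <- function(records, t, refs) {
  refset <- if (is.data.frame(refs)) refs$taxid else as.integer(refs)
  taxa <- unique(records$taxon_id)
  assigned <- vapply(taxa, function(x)
    closest_reference_ancestor(t, x, refset), integer(1))
  names(assigned) <- as.character(taxa)
  bin <- assigned[as.character(records$taxon_id)]
  out <- lapply(stats::setNames(refset, as.character(refset)),
                function(r) {
                  records[!is.na(bin) & bin == r, , drop = FALSE]
                })
  out$.discard <- records[is.na(bin), , drop = FALSE]
  out
}

#' Direct and cumulative GO term frequencies over a scope
#'
#' An annotation to term x contributes 1 to the cumulative count of
#' every ancestor-or-self of x, once per (annotation, ancestor) pair —
#' diamonds in the DAG do not double-count.
#'
#' @param records Annotation data.frame (already restricted to the
#'   scope: the whole corpus, or one reference node's bin).
#' @param g An `ontology_graph`.
#' @param scope Label stored on the table (`"GLOBAL"` or a taxid).
#' @param count_unit `"annotations"` (count lines, the default) or
#'   `"proteins"` (count distinct object ids per term).
#' @return A `frequency_table`: list with `scope`, `direct`,
#'   `cumulative` (named integer vectors over all non-obsolete terms).
#' @export
compute_frequencies <- function(records, g, scope = "GLOBAL",
                                count_unit = c("annotations",
                                               "proteins")) {
  count_unit <- match.arg(count_unit)
  live <- g$ids[!g$obsolete]
  direct <- stats::setNames(integer(length(live)), live)
  cumulative <- direct
  if (nrow(records)) {
    if (count_unit == "proteins") {
      records <- records[!duplicated(records[, c("object_id", "go_id")]),
                         , drop = FALSE]
    }
    unknown <- setdiff(unique(records$go_id), live)
    if (length(unknown)) {
      stop("annotations to unknown/obsolete terms reached the ",
           "frequency engine: ", paste(unknown, collapse = ", "))
    }
    tab <- table(records$go_id)
    direct[names(tab)] <- as.integer(tab)
    for (go in names(tab)) {
      up <- c(go, go_ancestors(g, go))
      cumulative[up] <- cumulative[up] + as.integer(tab[[go]])
    }
  }
  structure(list(scope = scope, direct = direct,
                 cumulative = cumulative, count_unit = count_unit),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("<frequency_table> scope ", x$scope, ": ",
      sum(x$direct), " annotations over ",
      sum(x$direct > 0L), " terms\n", sep = "")
  invisible(x)
}

#' Write a frequency table as TSV
#'
#' @param ft A `frequency_table`.
#' @param path Output path.
#' @export
write_frequency_table <- function(ft, path) {
  utils::write.table(
    data.frame(go_id = names(ft$direct), direct = unname(ft$direct),
               cumulative = unname(ft$cumulative)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive automatic never_in constraints for one reference node
#'
#' A term is marked `never_in` for the reference node when its
#' cumulative frequency over the whole cleaned corpus reaches
#' `threshold` (default 500) while its cumulative frequency inside the
#' reference node is exactly zero. The emitted list is pruned to
#' GO-topmost terms by default (a term whose emitted ancestor already
#' covers it is dropped; the expansion restores the closure).
#'
#' @param global_ft Corpus-wide `frequency_table`.
#' @param ref_ft The reference node's `frequency_table`.
#' @param ref_node Reference-node taxid.
#' @param threshold Minimum corpus-wide cumulative frequency (>= 1).
#' @param g The `ontology_graph` both tables were computed over.
#' @param prune Prune to topmost terms (default TRUE).
#' @return data.frame of constraint records (`taxon_id`, `go_id`,
#'   `relation = "never_in"`, `source = "automatic"`,
#'   `reference_node`, `scope = "subtree"`).
#' @export
derive_never_in <- function(global_ft, ref_ft, ref_node, threshold = 500L,
                            g, prune = TRUE) {
  if (threshold < 1L) stop("parameter error: threshold must be >= 1")
  stopifnot(identical(names(global_ft$cumulative),
                      names(ref_ft$cumulative)))
  hit <- names(global_ft$cumulative)[
    global_ft$cumulative >= threshold & ref_ft$cumulative == 0L]
  if (prune && length(hit)) {
    keep <- vapply(hit, function(go)
      !any(go_ancestors(g, go) %in% hit), logical(1))
    hit <- hit[keep]
  }
  if (length(hit) == 0L) {
    return(constraint_set()$records)
  }
  data.frame(taxon_id = as.integer(ref_node), go_id = sort(hit),
             relation = "never_in", source = "automatic",
             reference_node = as.integer(ref_node), scope = "subtree",
             stringsAsFactors = FALSE)
}

# GO-descendant closure of a term (term itself included).
go_closure_down <- function(g, go_id) {
  c(go_id, go_descendants(g, go_id))
}

#' Expand a constraint set to the full prohibited GO set of a taxon
#'
#' Resolution walks the three source tiers in priority order
#' (automatic, then consortium, then manual), applying within each tier
#' first the permissions (only_in inside its clade, allow) and then the
#' prohibitions (never_in; only_in outside its clade), so that a
#' never_in beats an only_in of the same tier while any higher tier
#' overrides everything below it. only_in records sharing a GO term are
#' grouped: the allowed region is the union of their subtrees.
#'
#' @param cs A `constraint_set`.
#' @param g An `ontology_graph`.
#' @param t A `taxonomy_tree`.
#' @param taxid Taxon whose prohibited set is wanted (merged ids
#'   redirected).
#' @return Character vector of prohibited GO ids (GO-descendant closed),
#'   sorted.
#' @export
expand_constraints <- function(cs, g, t, taxid) {
  x <- resolve_taxid(t, taxid)
  if (is.na(x)) stop("unknown taxid: ", taxid)
  lin <- tax_lineage(t, x)
  rec <- cs$records
  prohibited <- character()
  for (tier in c("automatic", "goc", "manual")) {
    r <- rec[rec$source == tier, , drop = FALSE]
    if (nrow(r) == 0L) next
    applies <- (r$scope == "subtree" & r$taxon_id %in% lin) |
      (r$scope == "node" & r$taxon_id == x)
    # permissions first: only_in inside its clade(s), then allow
    oi <- r[r$relation == "only_in", , drop = FALSE]
    oi_in <- character(); oi_out <- character()
    if (nrow(oi)) {
      for (go in unique(oi$go_id)) {
        allowed_here <- any(vapply(oi$taxon_id[oi$go_id == go],
                                   function(T) is_in_subtree(t, x, T),
                                   logical(1)))
        if (allowed_here) oi_in <- c(oi_in, go)
        else oi_out <- c(oi_out, go)
      }
    }
    for (go in oi_in) {
      prohibited <- setdiff(prohibited, go_closure_down(g, go))
    }
    al <- r[r$relation == "allow" & applies, , drop = FALSE]
    for (go in al$go_id) {
      prohibited <- setdiff(prohibited, go_closure_down(g, go))
    }
    # prohibitions
    ni <- r[r$relation == "never_in" & applies, , drop = FALSE]
    for (go in unique(c(ni$go_id, oi_out))) {
      prohibited <- union(prohibited, go_closure_down(g, go))
    }
  }
  sort(prohibited)
}

#' Write a constraint set in the tabular export format
#'
#' Columns: taxon_id, taxon_name, go_id, go_name, namespace, relation,
#' source, reference_node. Metadata is emitted as leading
#' `#key: value` lines.
#'
#' @param cs A `constraint_set`.
#' @param path Output path.
#' @param g,t Ontology and taxonomy for name columns (optional; names
#'   left blank when absent).
#' @export
write_constraints <- function(cs, path, g = NULL, t = NULL) {
  rec <- cs$records
  taxon_name <- if (!is.null(t)) {
    ifelse(as.character(rec$taxon_id) %in% names(t$sci_name),
           t$sci_name[as.character(rec$taxon_id)], "")
  } else ""
  go_name <- if (!is.null(g)) {
    ifelse(rec$go_id %in% g$ids, g$name[rec$go_id], "")
  } else ""
  namespace <- if (!is.null(g)) {
    ifelse(rec$go_id %in% g$ids, g$namespace[rec$go_id], "")
  } else ""
  con <- file(path, "wt")
  on.exit(close(con))
  for (k in names(cs$meta)) {
    writeLines(paste0("#", k, ": ", cs$meta[[k]]), con)
  }
  df <- data.frame(taxon_id = rec$taxon_id, taxon_name = taxon_name,
                   go_id = rec$go_id, go_name = go_name,
                   namespace = namespace, relation = rec$relation,
                   source = rec$source,
                   reference_node = rec$reference_node,
                   scope = rec$scope, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a constraint set written by [write_constraints()]
#'
#' @param path Constraint TSV path.
#' @return A `constraint_set`; `#key: value` header lines are restored
#'   into `meta`.
#' @export
read_constraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^#", "", m)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*:\\s*", "", kv)
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  constraint_set(data.frame(
    taxon_id = as.integer(df$taxon_id),
    go_id = as.character(df$go_id),
    relation = as.character(df$relation),
    source = as.character(df$source),
    reference_node = suppressWarnings(as.integer(df$reference_node)),
    scope = if (is.null(df$scope)) rep("subtree", nrow(df))
            else as.character(df$scope),
    stringsAsFactors = FALSE), meta = meta)
}
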