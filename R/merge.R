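# Conversion of only_in axioms, manual-constraint input, priority
# merging (manual > consortium > automatic) and the annotation audit.

#' Convert only_in axioms into compact never_in records
#'
#' `only_in(g, T)` means g is prohibited everywhere outside subtree(T).
#' The compact encoding emits, for every strict ancestor A of T on the
#' root path: a subtree-scoped `never_in(g)` on each child branch of A
#' off the path, plus a node-scoped `never_in(g)` on A itself (A is not
#' inside subtree(T) either). `only_in(g, root)` therefore yields no
#' records. Correctness contract: after expansion, g is prohibited for
#' taxon x iff x lies outside subtree(T).
#'
#' @param axioms data.frame with columns `go_id`, `relation`
#'   (rows with relation `"only_in"` are converted; `"never_in"` rows
#'   pass through unchanged), `taxon_id`.
#' @param t A `taxonomy_tree`.
#' @param source Source tag for the produced records (default `"goc"`).
#' @return data.frame of constraint records.
#' @export
convert_only_in <- function(axioms, t, source = "goc") {
  out <- list()
  for (i in seq_len(nrow(axioms))) {
    go <- axioms$go_id[i]
    T_raw <- axioms$taxon_id[i]
    T <- resolve_taxid(t, T_raw)
    if (is.na(T)) {
      stop("only_in axiom references unknown taxon ", T_raw,
           " (GO id ", go, ")")
    }
    if (axioms$relation[i] == "never_in") {
      out[[length(out) + 1L]] <- data.frame(
        taxon_id = T, go_id = go, relation = "never_in",
        source = source, reference_node = NA_integer_,
        scope = "subtree", stringsAsFactors = FALSE)
      next
    }
    path <- rev(tax_lineage(t, T))  # root ... T
    if (length(path) < 2L) next     # only_in on the root: no prohibition
    for (j in seq_len(length(path) - 1L)) {
      A <- path[j]
      next_on_path <- path[j + 1L]
      out[[length(out) + 1L]] <- data.frame(
        taxon_id = A, go_id = go, relation = "never_in",
        source = source, reference_node = NA_integer_,
        scope = "node", stringsAsFactors = FALSE)
      sibs <- setdiff(t$children[[as.character(A)]], next_on_path)
      if (length(sibs)) {
        out[[length(out) + 1L]] <- data.frame(
          taxon_id = sibs, go_id = go, relation = "never_in",
          source = source, reference_node = NA_integer_,
          scope = "subtree", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(constraint_set()$records)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  unique(res)
}

#' Read a manual-constraint configuration file
#'
#' One directive per line:
#' `<taxid or taxon name> <GO id> <never_in|only_in|allow>`,
#' whitespace-separated; `#` starts a comment; taxon names (which may
#' contain spaces) are resolved through the taxonomy's scientific
#' names.
#'
#' @param path Configuration file.
#' @param t A `taxonomy_tree`.
#' @return data.frame with columns `taxon_id`, `go_id`, `directive`.
#' @export
read_manual_constraints <- function(path, t) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (length(tok) < 3L) {
      stop("manual constraint line ", i, " needs ",
           "<taxon> <GO id> <directive>: '", ln, "'")
    }
    directive <- tok[length(tok)]
    go <- tok[length(tok) - 1L]
    taxon_tok <- paste(tok[seq_len(length(tok) - 2L)], collapse = " ")
    if (!directive %in% c("never_in", "only_in", "allow")) {
      stop("manual constraint line ", i, ": unknown directive '",
           directive, "'")
    }
    if (!grepl("^GO:\\d{7}$", go)) {
      stop("manual constraint line ", i, ": malformed GO id '", go, "'")
    }
    taxid <- if (grepl("^\\d+$", taxon_tok)) {
      r <- resolve_taxid(t, as.integer(taxon_tok))
      if (is.na(r)) stop("manual constraint line ", i,
                         ": unknown taxid ", taxon_tok)
      r
    } else {
      tryCatch(taxid_by_name(t, taxon_tok),
               error = function(e) stop("manual constraint line ", i,
                                        ": ", conditionMessage(e)))
    }
    out[[length(out) + 1L]] <- data.frame(
      taxon_id = taxid, go_id = go, directive = directive,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(taxon_id = integer(), go_id = character(),
                      directive = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ancestor-or-self relation in either direction
go_related <- function(g, a, b) {
  a == b || a %in% go_ancestors(g, b) || b %in% go_ancestors(g, a)
}
tax_related <- function(t, a, b) {
  is_in_subtree(t, a, b) || is_in_subtree(t, b, a)
}

#' Merge automatic, consortium and manual constraints
#'
#' Combines the three tiers into one `constraint_set` under the strict
#' priority manual > consortium (goc) > automatic. Resolution happens
#' at expansion time ([expand_constraints()] walks the tiers in
#' order); merging validates the inputs, tags provenance, warns on
#' consortium-internal never_in/only_in collisions (never_in wins) and
#' errors on contradictory manual directives for the identical
#' (taxon, GO) pair. A conflict report lists every lower-tier record
#' overridden by a higher-tier permission or prohibition on an
#' overlapping (taxon subtree, GO closure) region.
#'
#' @param auto `constraint_set` (or records data.frame) of automatic
#'   never_in records.
#' @param goc data.frame of consortium records (axioms from
#'   [extract_goc_axioms()], already converted or raw: raw `only_in`
#'   rows are kept as native only_in records; expansion handles their
#'   semantics directly).
#' @param manual data.frame from [read_manual_constraints()].
#' @param t A `taxonomy_tree`.
#' @param g An `ontology_graph`.
#' @param meta Provenance metadata list.
#' @return A `constraint_set` with the overridden-record report attached
#'   as its `conflicts` data.frame.
#' @export
merge_constraints <- function(auto, goc = NULL, manual = NULL, t, g,
                              meta = list()) {
  auto_rec <- if (inherits(auto, "constraint_set")) auto$records
              else auto
  if (is.null(auto_rec)) auto_rec <- constraint_set()$records
  goc_rec <- constraint_set()$records
  if (!is.null(goc) && nrow(goc)) {
    gr <- if (inherits(goc, "constraint_set")) goc$records else goc
    if (is.null(gr$source)) {
      # raw axiom table (go_id, relation, taxon_id)
      T_res <- resolve_taxid(t, gr$taxon_id)
      if (anyNA(T_res)) {
        stop("consortium axiom references unknown taxon: ",
             paste(gr$taxon_id[is.na(T_res)], collapse = ", "))
      }
      gr <- data.frame(taxon_id = T_res, go_id = gr$go_id,
                       relation = gr$relation, source = "goc",
                       reference_node = NA_integer_, scope = "subtree",
                       stringsAsFactors = FALSE)
    }
    both <- intersect(gr$go_id[gr$relation == "never_in"],
                      gr$go_id[gr$relation == "only_in"])
    if (length(both)) {
      warning("consortium-internal never_in/only_in collision on ",
              paste(both, collapse = ", "), "; never_in wins")
    }
    goc_rec <- gr
  }
  man_rec <- constraint_set()$records
  if (!is.null(manual) && nrow(manual)) {
    key <- paste(manual$taxon_id, manual$go_id)
    for (k in unique(key[duplicated(key)])) {
      d <- unique(manual$directive[key == k])
      if (length(d) > 1L) {
        stop("contradictory manual directives for (", k, "): ",
             paste(d, collapse = " vs "))
      }
    }
    manual <- manual[!duplicated(key), , drop = FALSE]
    man_rec <- data.frame(taxon_id = manual$taxon_id,
                          go_id = manual$go_id,
                          relation = manual$directive, source = "manual",
                          reference_node = NA_integer_,
                          scope = "subtree", stringsAsFactors = FALSE)
  }
  all_rec <- rbind(auto_rec, goc_rec, man_rec)
  cs <- constraint_set(all_rec, meta = meta)
  cs$conflicts <- conflict_report(cs, g, t)
  cs
}

# Lower-tier records overridden by a higher-tier record acting on an
# overlapping (taxon, GO-closure) region with opposite effect.
conflict_report <- function(cs, g, t) {
  rec <- cs$records
  tier <- c(automatic = 1L, goc = 2L, manual = 3L)
  rec$.tier <- tier[rec$source]
  out <- list()
  prohibits <- rec$relation == "never_in"
  for (i in seq_len(nrow(rec))) {
    hi <- rec[rec$.tier > rec$.tier[i], , drop = FALSE]
    if (nrow(hi) == 0L) next
    for (j in seq_len(nrow(hi))) {
      # opposite effect: prohibition vs permission
      opposite <- prohibits[i] != (hi$relation[j] == "never_in")
      if (!opposite) next
      if (!go_related(g, rec$go_id[i], hi$go_id[j])) next
      if (!tax_related(t, rec$taxon_id[i], hi$taxon_id[j])) next
      out[[length(out) + 1L]] <- data.frame(
        overridden_source = rec$source[i],
        overridden_relation = rec$relation[i],
        overridden_taxon = rec$taxon_id[i],
        overridden_go = rec$go_id[i],
        by_source = hi$source[j], by_relation = hi$relation[j],
        by_taxon = hi$taxon_id[j], by_go = hi$go_id[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(overridden_source = character(),
                      overridden_relation = character(),
                      overridden_taxon = integer(),
                      overridden_go = character(),
                      by_source = character(), by_relation = character(),
                      by_taxon = integer(), by_go = character(),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, out))
}

#' Audit an annotation set against a constraint set
#'
#' Every annotation (NOT-qualified lines excluded — a NOT annotation
#' asserts absence, so it cannot violate a prohibition) whose GO term
#' falls inside its organism's prohibited set is reported, with the
#' violated topmost constraint and its source. Annotations whose GO id
#' or taxid cannot be resolved are skipped.
#'
#' @param records Annotation data.frame from [read_gaf()] (uncleaned).
#' @param cs A merged `constraint_set`.
#' @param g An `ontology_graph`.
#' @param t A `taxonomy_tree`.
#' @return data.frame of violations: `object_id`, `taxon_id`, `go_id`,
#'   `evidence_code`, `violated_constraint_go`, `relation`, `source`.
#' @export
audit_annotations <- function(records, cs, g, t) {
  quals <- strsplit(records$qualifiers, "|", fixed = TRUE)
  has_not <- vapply(quals, function(q) "NOT" %in% q, logical(1))
  records <- records[!has_not, , drop = FALSE]
  records$go_id <- resolve_go_id(g, records$go_id)
  records$taxon_id <- resolve_taxid(t, records$taxon_id)
  records <- records[!is.na(records$go_id) & !is.na(records$taxon_id), ,
                     drop = FALSE]
  exp_cache <- new.env(parent = emptyenv())
  out <- list()
  for (i in seq_len(nrow(records))) {
    x <- records$taxon_id[i]
    key <- as.character(x)
    banned <- exp_cache[[key]]
    if (is.null(banned)) {
      banned <- expand_constraints(cs, g, t, x)
      exp_cache[[key]] <- banned
    }
    go <- records$go_id[i]
    if (!(go %in% banned)) next
    src <- attribute_violation(cs, g, t, x, go)
    out[[length(out) + 1L]] <- data.frame(
      object_id = records$object_id[i], taxon_id = x, go_id = go,
      evidence_code = records$evidence_code[i],
      violated_constraint_go = src$go, relation = src$relation,
      source = src$source, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(object_id = character(), taxon_id = integer(),
                      go_id = character(), evidence_code = character(),
                      violated_constraint_go = character(),
                      relation = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Highest-priority record responsible for prohibiting `go` at taxon `x`.
attribute_violation <- function(cs, g, t, x, go) {
  rec <- cs$records
  lin <- tax_lineage(t, x)
  for (tier in c("manual", "goc", "automatic")) {
    r <- rec[rec$source == tier, , drop = FALSE]
    if (nrow(r) == 0L) next
    applies <- (r$scope == "subtree" & r$taxon_id %in% lin) |
      (r$scope == "node" & r$taxon_id == x)
    ni <- r[r$relation == "never_in" & applies, , drop = FALSE]
    for (j in seq_len(nrow(ni))) {
      if (go %in% go_closure_down(g, ni$go_id[j])) {
        return(list(go = ni$go_id[j], relation = "never_in",
                    source = tier))
      }
    }
    oi <- r[r$relation == "only_in", , drop = FALSE]
    for (gid in unique(oi$go_id)) {
      inside <- any(vapply(oi$taxon_id[oi$go_id == gid],
                           function(T) is_in_subtree(t, x, T),
                           logical(1)))
      if (!inside && go %in% go_closure_down(g, gid)) {
        return(list(go = gid, relation = "only_in", source = tier))
      }
    }
  }
  list(go = NA_character_, relation = NA_character_,
       source = NA_character_)
}

#' Write an audit violation report as TSV
#'
#' @param violations data.frame from [audit_annotations()].
#' @param path Output path.
#' @export
write_violations <- function(violations, path) {
  utils::write.table(violations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
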