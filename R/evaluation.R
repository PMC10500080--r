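# Species-centric benchmark: pool scored per-protein GO predictions
# into one non-redundant set per species, filter by taxon constraints,
# and score against an ancestor-closed ground truth with the CAFA
# metrics Fmax, weighted Fmax and Smin per subontology.

#' Aggregate per-protein predictions into a species prediction
#'
#' The species-level score of a GO term is the highest score any
#' protein of the species obtained for it; ancestor closure then lifts
#' each term's score onto its ancestors (a parent's score is at least
#' the maximum over its scored descendants), the usual consistency
#' requirement for threshold sweeps. Namespace roots are dropped.
#'
#' @param predictions data.frame with columns `protein` (ignored beyond
#'   the max-pooling), `go_id`, `score` in \[0,1\].
#' @param taxon_id The species' taxid.
#' @param g An `ontology_graph` (for alt-id resolution, namespaces and
#'   closure).
#' @param propagate Apply ancestor closure (default TRUE).
#' @return A `species_prediction`: list with `taxon_id` and `scores`
#'   (named numeric vector over GO ids).
#' @export
aggregate_species <- function(predictions, taxon_id, g,
                              propagate = TRUE) {
  if (nrow(predictions) &&
      (any(predictions$score < 0) || any(predictions$score > 1))) {
    stop("input error: prediction scores must lie in [0, 1]")
  }
  scores <- numeric()
  if (nrow(predictions)) {
    go <- resolve_go_id(g, predictions$go_id)
    keep <- !is.na(go) & !g$obsolete[go]
    go <- go[keep]
    sc <- predictions$score[keep]
    if (length(go)) {
      scores <- vapply(split(sc, go), max, numeric(1))
      if (propagate) {
        lifted <- scores
        for (term in names(scores)) {
          up <- go_ancestors(g, term)
          for (a in up) {
            cur <- if (a %in% names(lifted)) lifted[[a]] else 0
            if (scores[[term]] > cur) lifted[[a]] <- scores[[term]]
          }
        }
        scores <- lifted
      }
      scores <- scores[setdiff(names(scores), unname(g$roots))]
    }
  }
  structure(list(taxon_id = as.integer(taxon_id), scores = scores),
            class = "species_prediction")
}

#' Remove constraint-prohibited terms from a species prediction
#'
#' @param sp A `species_prediction`.
#' @param cs A merged `constraint_set`.
#' @param g An `ontology_graph`.
#' @param t A `taxonomy_tree`.
#' @return The filtered `species_prediction` (idempotent).
#' @export
apply_constraint_filter <- function(sp, cs, g, t) {
  banned <- expand_constraints(cs, g, t, sp$taxon_id)
  sp$scores <- sp$scores[setdiff(names(sp$scores), banned)]
  sp
}

#' Information content from corpus frequencies
#'
#' `ic(term) = -log2((cumulative[term] + 1) / (cumulative[root] + 1))`
#' with the root of the term's namespace; the +1 smoothing keeps
#' unannotated terms finite. Monotone non-decreasing from root to
#' leaves because cumulative counts are monotone non-increasing.
#'
#' @param global_ft Corpus-wide `frequency_table`.
#' @param g An `ontology_graph`.
#' @return An `ic_table`: named numeric vector of bits over all
#'   non-obsolete terms.
#' @export
information_content <- function(global_ft, g) {
  cum <- global_ft$cumulative
  if (length(cum) == 0L) stop("empty frequency table")
  root_tot <- stats::setNames(cum[unname(g$roots)], names(g$roots))
  ns <- g$namespace[names(cum)]
  denom <- as.numeric(root_tot[ns]) + 1
  ic <- -log2((as.numeric(cum) + 1) / denom)
  ic[is.na(ic)] <- 0
  structure(stats::setNames(pmax(ic, 0), names(cum)),
            class = "ic_table")
}

ic_of <- function(ic, terms) {
  if (length(terms) == 0L) return(numeric())
  v <- unclass(ic)[terms]
  v[is.na(v)] <- 0
  v
}

#' Threshold-sweep metric curve for one species and namespace
#'
#' Sweeps a descending score grid (the distinct predicted scores,
#' thinned to at most 101 points); at each threshold tau the predicted
#' set is `P = {g : score >= tau}` and, against truth `T`:
#' precision `|P∩T|/|P|` (thresholds with empty P are skipped),
#' recall `|P∩T|/|T|`, weighted variants with cardinalities replaced by
#' information-content sums, remaining uncertainty
#' `ru = sum ic(T \\ P)` and misinformation `mi = sum ic(P \\ T)`.
#' Summaries: `F_max = max 2·pr·rc/(pr+rc)`, `wF_max` analogous,
#' `S_min = min sqrt(ru^2 + mi^2)`.
#'
#' @param sp A `species_prediction` (already namespace-restricted or
#'   not; `namespace` selects).
#' @param truth Character vector of ground-truth GO ids
#'   (ancestor-closed, roots excluded) or a `ground_truth` object.
#' @param ic An `ic_table`.
#' @param g An `ontology_graph`.
#' @param namespace One of the three GO namespaces, or NULL to use all
#'   terms as given.
#' @return A `metric_curve`: list with the sweep data.frame
#'   (`threshold`, `precision`, `recall`, `wprecision`, `wrecall`,
#'   `ru`, `mi`) and summaries `fmax`, `wfmax`, `smin`.
#' @export
metric_curve <- function(sp, truth, ic, g, namespace = NULL) {
  scores <- sp$scores
  if (!is.null(namespace)) {
    scores <- scores[g$namespace[names(scores)] == namespace]
    truth <- truth[g$namespace[truth] == namespace]
  }
  truth <- setdiff(truth, unname(g$roots))
  if (length(truth) == 0L) {
    stop("empty ground truth: metrics undefined")
  }
  taus <- sort(unique(as.numeric(scores)), decreasing = TRUE)
  if (length(taus) > 101L) {
    taus <- taus[unique(round(seq(1L, length(taus), length.out = 101L)))]
  }
  if (length(taus) == 0L) taus <- 1
  ic_T <- sum(ic_of(ic, truth))
  rows <- lapply(taus, function(tau) {
    P <- names(scores)[scores >= tau]
    tp <- intersect(P, truth)
    fp <- setdiff(P, truth)
    fn <- setdiff(truth, P)
    pr <- if (length(P)) length(tp) / length(P) else NA_real_
    rc <- length(tp) / length(truth)
    ic_P <- sum(ic_of(ic, P))
    wpr <- if (length(P) && ic_P > 0) sum(ic_of(ic, tp)) / ic_P
           else NA_real_
    wrc <- if (ic_T > 0) sum(ic_of(ic, tp)) / ic_T else NA_real_
    data.frame(threshold = tau, precision = pr, recall = rc,
               wprecision = wpr, wrecall = wrc,
               ru = sum(ic_of(ic, fn)), mi = sum(ic_of(ic, fp)))
  })
  curve <- do.call(rbind, rows)
  f <- function(p, r) ifelse(is.na(p) | (p + r) == 0, NA_real_,
                             2 * p * r / (p + r))
  fvals <- f(curve$precision, curve$recall)
  wfvals <- f(curve$wprecision, curve$wrecall)
  fmax <- if (all(is.na(fvals))) 0 else max(fvals, na.rm = TRUE)
  wfmax <- if (all(is.na(wfvals))) 0 else max(wfvals, na.rm = TRUE)
  smin <- min(sqrt(curve$ru^2 + curve$mi^2))
  structure(list(curve = curve, fmax = fmax, wfmax = wfmax,
                 smin = smin), class = "metric_curve")
}

#' @export
print.metric_curve <- function(x, ...) {
  cat(sprintf("<metric_curve> Fmax %.3f  wFmax %.3f  Smin %.3f (%d thresholds)\n",
              x$fmax, x$wfmax, x$smin, nrow(x$curve)))
  invisible(x)
}

#' Read a prediction file (protein, go_id, score TSV)
#'
#' @param path TSV without header, or with a `protein`/`go_id`/`score`
#'   header.
#' @return data.frame with columns `protein`, `go_id`, `score`.
#' @export
read_predictions <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("protein", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("protein", "go_id", "score")
  df$score <- as.numeric(df$score)
  df
}

#' Load an ancestor-closed ground truth per species
#'
#' @param path A GAF file or a two-column TSV (`taxon_id`, `go_id`).
#' @param g An `ontology_graph`.
#' @param t Optional `taxonomy_tree` for taxid redirects.
#' @param format `"gaf"` or `"tsv"`; guessed from the first line.
#' @return Named list taxid -> character vector of GO ids, closed under
#'   propagating-relation ancestors, roots excluded.
#' @export
read_ground_truth <- function(path, g, t = NULL,
                              format = c("auto", "gaf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    nf <- length(strsplit(first, "\t", fixed = TRUE)[[1L]])
    format <- if (startsWith(first, "!") || nf >= 15L) "gaf" else "tsv"
  }
  if (format == "gaf") {
    rec <- read_gaf(path, t)
    df <- data.frame(taxon_id = rec$taxon_id, go_id = rec$go_id,
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = FALSE,
                            col.names = c("taxon_id", "go_id"),
                            stringsAsFactors = FALSE)
    if (!grepl("^\\d+$", df$taxon_id[1L])) df <- df[-1L, , drop = FALSE]
    df$taxon_id <- as.integer(df$taxon_id)
  }
  df$go_id <- resolve_go_id(g, df$go_id)
  df <- df[!is.na(df$go_id) & !g$obsolete[df$go_id], , drop = FALSE]
  lapply(split(df$go_id, df$taxon_id), function(terms) {
    closed <- unique(unlist(lapply(unique(terms), function(x)
      c(x, go_ancestors(g, x)))))
    sort(setdiff(closed, unname(g$roots)))
  })
}

#' Evaluate a constraint-filtered benchmark
#'
#' For each species' prediction file, computes Fmax, wFmax and Smin
#' per subontology, unfiltered and under each supplied constraint set.
#'
#' @param pred_files Named character vector: names are taxids, values
#'   prediction-file paths (or a named list of prediction data.frames).
#' @param truth Ground-truth list from [read_ground_truth()].
#' @param constraint_sets Named list of `constraint_set` objects (may
#'   be empty; the unfiltered rows are always produced).
#' @param g An `ontology_graph`.
#' @param t A `taxonomy_tree`.
#' @param ic An `ic_table`.
#' @return data.frame: `species`, `namespace`, `filter`, `fmax`,
#'   `wfmax`, `smin`.
#' @export
evaluate_benchmark <- function(pred_files, truth, constraint_sets = list(),
                               g, t, ic) {
  out <- list()
  for (taxkey in names(pred_files)) {
    taxid <- as.integer(taxkey)
    if (!(taxkey %in% names(truth))) {
      warning("species ", taxkey, " absent from ground truth; skipped")
      next
    }
    preds <- pred_files[[taxkey]]
    if (is.character(preds)) preds <- read_predictions(preds)
    sp <- aggregate_species(preds, taxid, g)
    variants <- c(list(unfilt = sp),
                  lapply(constraint_sets, function(cs)
                    apply_constraint_filter(sp, cs, g, t)))
    for (ns in GO_NAMESPACES) {
      truth_ns <- truth[[taxkey]][g$namespace[truth[[taxkey]]] == ns]
      if (length(truth_ns) == 0L) next
      for (v in names(variants)) {
        mc <- metric_curve(variants[[v]], truth_ns, ic, g,
                           namespace = ns)
        out[[length(out) + 1L]] <- data.frame(
          species = taxid, namespace = ns, filter = v,
          fmax = mc$fmax, wfmax = mc$wfmax, smin = mc$smin,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(species = integer(), namespace = character(),
                      filter = character(), fmax = numeric(),
                      wfmax = numeric(), smin = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
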