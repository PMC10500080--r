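# Independent brute-force oracles and tiny hand-built fixtures. The
# oracles use their own recursive traversals and never call the
# package's closure machinery, so tests compare two separate routes.

ROOT_CC <- "GO:0005575"
ROOT_BP <- "GO:0008150"
ROOT_MF <- "GO:0003674"

# ---- oracle traversals -------------------------------------------------

# reachability by plain recursive DFS with a visited set
oracle_reach <- function(adj, from) {
  visited <- character()
  walk <- function(x) {
    for (y in adj[[x]]) {
      if (!(y %in% visited)) {
        visited <<- c(visited, y)
        walk(y)
      }
    }
  }
  walk(from)
  sort(visited)
}

oracle_descendants <- function(g, id) oracle_reach(g$children, id)
oracle_ancestors <- function(g, id) oracle_reach(g$parents, id)
oracle_closure_down <- function(g, id) sort(c(id, oracle_descendants(g, id)))

oracle_lineage <- function(t, x) {
  out <- integer()
  cur <- x
  repeat {
    out <- c(out, cur)
    p <- t$parent[[as.character(cur)]]
    if (p == cur) break
    cur <- p
  }
  out
}

oracle_subtree <- function(t, a) {
  t$taxids[vapply(t$taxids, function(x) a %in% oracle_lineage(t, x),
                  logical(1))]
}

# ---- sequential-overwrite verdict matrix oracle ------------------------
# Fully expands a constraint set over (all fixture taxa x all terms):
# apply automatic, overwrite with consortium, overwrite with manual.
# Within a tier, clears (allow; only_in inside its clades) run before
# sets (never_in; only_in outside), and only_in records sharing a GO
# term pool their subtrees into one allowed region.
oracle_verdict_matrix <- function(cs, g, t) {
  taxa <- t$taxids
  terms <- g$ids[!g$obsolete]
  M <- matrix(FALSE, nrow = length(taxa), ncol = length(terms),
              dimnames = list(as.character(taxa), terms))
  rec <- cs$records
  for (tier in c("automatic", "goc", "manual")) {
    r <- rec[rec$source == tier, , drop = FALSE]
    if (nrow(r) == 0L) next
    oi <- r[r$relation == "only_in", , drop = FALSE]
    allowed_region <- list()
    for (go in unique(oi$go_id)) {
      allowed_region[[go]] <- unique(unlist(
        lapply(oi$taxon_id[oi$go_id == go],
               function(T) oracle_subtree(t, T))))
    }
    # clears
    for (go in names(allowed_region)) {
      rows <- as.character(allowed_region[[go]])
      M[rows, intersect(oracle_closure_down(g, go), terms)] <- FALSE
    }
    al <- r[r$relation == "allow", , drop = FALSE]
    for (j in seq_len(nrow(al))) {
      rows <- as.character(oracle_subtree(t, al$taxon_id[j]))
      M[rows, intersect(oracle_closure_down(g, al$go_id[j]),
                        terms)] <- FALSE
    }
    # sets
    ni <- r[r$relation == "never_in", , drop = FALSE]
    for (j in seq_len(nrow(ni))) {
      rows <- if (identical(ni$scope[j], "node")) {
        as.character(ni$taxon_id[j])
      } else {
        as.character(oracle_subtree(t, ni$taxon_id[j]))
      }
      M[rows, intersect(oracle_closure_down(g, ni$go_id[j]),
                        terms)] <- TRUE
    }
    for (go in names(allowed_region)) {
      rows <- as.character(setdiff(taxa, allowed_region[[go]]))
      M[rows, intersect(oracle_closure_down(g, go), terms)] <- TRUE
    }
  }
  M
}

oracle_expand <- function(cs, g, t, x) {
  M <- oracle_verdict_matrix(cs, g, t)
  sort(colnames(M)[M[as.character(x), ]])
}

# ---- naive per-threshold metric oracle ---------------------------------
oracle_metrics <- function(scores, truth, ic) {
  taus <- sort(unique(as.numeric(scores)), decreasing = TRUE)
  if (length(taus) == 0L) taus <- 1
  best_f <- 0; best_wf <- 0; best_s <- Inf
  icv <- function(x) {
    v <- unclass(ic)[x]; v[is.na(v)] <- 0; sum(v)
  }
  for (tau in taus) {
    P <- names(scores)[scores >= tau]
    tp <- intersect(P, truth)
    rc <- length(tp) / length(truth)
    if (length(P) > 0) {
      pr <- length(tp) / length(P)
      if (pr + rc > 0) best_f <- max(best_f, 2 * pr * rc / (pr + rc))
      if (icv(P) > 0 && icv(truth) > 0) {
        wpr <- icv(tp) / icv(P); wrc <- icv(tp) / icv(truth)
        if (wpr + wrc > 0) {
          best_wf <- max(best_wf, 2 * wpr * wrc / (wpr + wrc))
        }
      }
    }
    ru <- icv(setdiff(truth, P)); mi <- icv(setdiff(P, truth))
    best_s <- min(best_s, sqrt(ru^2 + mi^2))
  }
  list(fmax = best_f, wfmax = best_wf, smin = best_s)
}

# ---- tiny hand-built fixtures ------------------------------------------

# Minimal OBO text: 3 roots plus BP terms A -> B -> C and a diamond
# A -> {B, C2} -> D, an obsolete term, and one alt_id. Layout:
#   GO:0000001 (A)  is_a BP-root           alt_id GO:0000099
#   GO:0000002 (B)  is_a A
#   GO:0000003 (C)  is_a B
#   GO:0000004 (C2) part_of A
#   GO:0000005 (D)  is_a B, is_a C2        (diamond under A)
#   GO:0000010 (MF leaf), GO:0000011 (CC leaf)
#   GO:0000008 obsolete
tiny_obo <- function(path = tempfile(fileext = ".obo"),
                     extra = character()) {
  writeLines(c(
    "format-version: 1.4",
    "",
    "[Term]", paste0("id: ", ROOT_BP), "name: biological_process",
    "namespace: biological_process",
    "",
    "[Term]", paste0("id: ", ROOT_MF), "name: molecular_function",
    "namespace: molecular_function",
    "",
    "[Term]", paste0("id: ", ROOT_CC), "name: cellular_component",
    "namespace: cellular_component",
    "",
    "[Term]", "id: GO:0000001", "name: A", "alt_id: GO:0000099",
    "namespace: biological_process", paste0("is_a: ", ROOT_BP),
    "",
    "[Term]", "id: GO:0000002", "name: B",
    "namespace: biological_process", "is_a: GO:0000001 ! A",
    "",
    "[Term]", "id: GO:0000003", "name: C",
    "namespace: biological_process", "is_a: GO:0000002",
    "",
    "[Term]", "id: GO:0000004", "name: C2",
    "namespace: biological_process",
    "relationship: part_of GO:0000001",
    "",
    "[Term]", "id: GO:0000005", "name: D",
    "namespace: biological_process", "is_a: GO:0000002",
    "is_a: GO:0000004",
    "",
    "[Term]", "id: GO:0000010", "name: mf_leaf",
    "namespace: molecular_function", paste0("is_a: ", ROOT_MF),
    "",
    "[Term]", "id: GO:0000011", "name: cc_leaf",
    "namespace: cellular_component", paste0("is_a: ", ROOT_CC),
    "",
    "[Term]", "id: GO:0000008", "name: gone",
    "namespace: biological_process", "is_obsolete: true",
    extra), path)
  path
}

# Taxonomy: 1 root; 2 Bacteria-like (species 7, 562 below); 3
# Eukaryota-like; 4 Fungi-like under 3 (species 5 = yeast-like);
# 6 human-like under 3. merged.dmp: 666 -> 562.
tiny_taxdump <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- c("1\t|\t1\t|\tno rank\t|",
             "2\t|\t1\t|\tsuperkingdom\t|",
             "3\t|\t1\t|\tsuperkingdom\t|",
             "4\t|\t3\t|\tkingdom\t|",
             "5\t|\t4\t|\tspecies\t|",
             "6\t|\t3\t|\tspecies\t|",
             "7\t|\t2\t|\tspecies\t|",
             "562\t|\t2\t|\tspecies\t|")
  nms <- c("1\t|\troot\t|\t\t|\tscientific name\t|",
           "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
           "3\t|\tEukaryota\t|\t\t|\tscientific name\t|",
           "4\t|\tFungi\t|\t\t|\tscientific name\t|",
           "5\t|\tyeastlike\t|\t\t|\tscientific name\t|",
           "6\t|\thumanlike\t|\t\t|\tscientific name\t|",
           "7\t|\tpseudomonaslike\t|\t\t|\tscientific name\t|",
           "562\t|\tcolilike\t|\t\t|\tscientific name\t|")
  writeLines(nodes, file.path(dir, "nodes.dmp"))
  writeLines(nms, file.path(dir, "names.dmp"))
  writeLines("666\t|\t562\t|", file.path(dir, "merged.dmp"))
  dir
}

tiny_taxonomy <- function(dir = tiny_taxdump()) {
  load_taxonomy(file.path(dir, "nodes.dmp"),
                file.path(dir, "names.dmp"),
                file.path(dir, "merged.dmp"))
}

gaf_text_line <- function(obj, go, taxon, evidence = "IEA",
                          qualifier = "involved_in", db = "UniProtKB",
                          assigned_by = "UniProt") {
  paste(db, obj, obj, qualifier, go, "PMID:1", evidence, "", "P", "",
        "", "protein", paste0("taxon:", taxon), "20240101",
        assigned_by, "", "", sep = "\t")
}

write_gaf_fixture <- function(lines, path = tempfile(fileext = ".gaf")) {
  writeLines(c("!gaf-version: 2.2", lines), path)
  path
}

# annotation data.frame shaped like read_gaf() output
ann_df <- function(go_id, taxon_id = 5L, object_id = "P1",
                   evidence = "IEA") {
  n <- if (length(go_id)) {
    max(length(go_id), length(taxon_id), length(object_id))
  } else 0L
  data.frame(db = rep("UniProtKB", n),
             object_id = rep_len(object_id, n),
             object_symbol = rep_len(object_id, n),
             qualifiers = rep("involved_in", n),
             go_id = rep_len(go_id, n),
             evidence_code = rep_len(evidence, n),
             taxon_id = rep_len(as.integer(taxon_id), n),
             assigned_by = rep("UniProt", n),
             stringsAsFactors = FALSE)
}

# constraint records row builder
crec <- function(taxon_id, go_id, relation = "never_in",
                 source = "automatic", scope = "subtree",
                 reference_node = NA_integer_) {
  data.frame(taxon_id = as.integer(taxon_id), go_id = go_id,
             relation = relation, source = source,
             reference_node = as.integer(reference_node), scope = scope,
             stringsAsFactors = FALSE)
}
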