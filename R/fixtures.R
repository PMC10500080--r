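# Deterministic generators for synthetic ontologies, taxonomies and GAF
# corpora, plus a naive brute-force manifest of the constraints the
# derivation engine must and must not emit on the generated corpus. The
# manifest code deliberately uses its own recursive traversals (no
# shared closure machinery) so it can serve as an independent oracle.

#' Specification for a synthetic fixture bundle
#'
#' @param seed Integer seed; identical spec + seed give byte-identical
#'   files.
#' @param n_terms Named integer vector: non-root terms per namespace.
#' @param depth Maximum depth of the term DAG below each root.
#' @param diamond_frac Probability that a term gets a second parent
#'   (creating diamonds); 0 gives a tree.
#' @param n_obsolete Number of obsolete terms to append.
#' @param n_alt Number of terms carrying an alt_id.
#' @param axioms Optional data.frame (`go_id`, `relation`, `taxon_id`)
#'   of consortium-style taxon-constraint axioms to embed in the
#'   ontology file. `go_id` may be given as an index (integer) into the
#'   generated terms.
#' @param n_taxa Number of taxonomy nodes (including root 1).
#' @param n_ref Number of designated reference nodes.
#' @param n_lines Number of signal GAF lines.
#' @param noise Named list of extra dirty-line counts:
#'   `nd`, `not`, `root`, `rnacentral`, `env`, `unknown_taxon`,
#'   `obsolete`, `malformed`.
#' @param threshold Global cumulative-frequency cutoff used by the
#'   manifest brute force (the derivation default, 500, is rarely
#'   reachable on desk-size corpora, so fixtures default to 50).
#' @param n_planted Number of planted (reference node, term) exclusion
#'   patterns: the clade below the reference node receives no
#'   annotation to the term or its descendants, so a sufficiently
#'   frequent planted term must come out as `never_in`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_terms = c(biological_process = 18L,
                                     molecular_function = 12L,
                                     cellular_component = 12L),
                         depth = 4L, diamond_frac = 0.15,
                         n_obsolete = 1L, n_alt = 1L,
                         axioms = NULL,
                         n_taxa = 22L, n_ref = 3L,
                         n_lines = 700L,
                         noise = list(nd = 4L, not = 4L, root = 3L,
                                      rnacentral = 3L, env = 3L,
                                      unknown_taxon = 2L, obsolete = 2L,
                                      malformed = 1L),
                         threshold = 50L,
                         n_planted = 2L) {
  stopifnot(sum(n_terms) >= 3L, n_taxa >= 2L, threshold >= 1L)
  structure(list(seed = as.integer(seed), n_terms = n_terms,
                 depth = depth, diamond_frac = diamond_frac,
                 n_obsolete = n_obsolete, n_alt = n_alt,
                 axioms = axioms, n_taxa = as.integer(n_taxa),
                 n_ref = n_ref, n_lines = n_lines, noise = noise,
                 threshold = threshold, n_planted = n_planted),
            class = "fixture_spec")
}

# sample() without the scalar-x surprise
sample1 <- function(x, size = 1L, prob = NULL) {
  x[sample.int(length(x), size, prob = prob)]
}

with_fixture_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic ontology
#'
#' Writes a valid OBO 1.4 file with the three namespace roots, a random
#' acyclic is_a/part_of DAG per namespace, optional obsolete terms,
#' alt_ids, and embedded taxon-constraint axiom lines.
#'
#' @param spec A [fixture_spec()].
#' @param path Output OBO path.
#' @return The loaded `ontology_graph` (the file is parsed back through
#'   the real reader so the parser path is exercised), invisibly
#'   carrying `path`.
#' @export
make_ontology <- function(spec, path) {
  with_fixture_rng(spec$seed + 11L, {
    lines <- c("format-version: 1.4",
               "ontology: synthetic-go-fixture")
    counter <- 100L
    term_ids <- character()
    term_ns <- character()
    level_of <- list()
    for (ns in GO_NAMESPACES) {
      root <- GO_ROOTS[[ns]]
      lines <- c(lines, "", "[Term]", paste0("id: ", root),
                 paste0("name: ", ns, "_root"),
                 paste0("namespace: ", ns))
      k <- spec$n_terms[[ns]]
      if (is.null(k) || k == 0L) next
      ids <- sprintf("GO:%07d", counter + seq_len(k)); counter <- counter + k
      lvl <- integer(k)
      for (i in seq_len(k)) {
        # parent drawn from terms strictly shallower, root eligible
        shallower <- c(root, ids[seq_len(i - 1L)][
          lvl[seq_len(i - 1L)] < spec$depth])
        p1 <- sample1(shallower)
        lvl[i] <- if (p1 == root) 1L else
          lvl[match(p1, ids)] + 1L
        rel <- character()
        if (length(shallower) > 1L &&
            stats::runif(1) < spec$diamond_frac) {
          p2 <- sample1(setdiff(shallower, p1))
          rel <- if (stats::runif(1) < 0.5) {
            paste0("is_a: ", p2)
          } else {
            paste0("relationship: part_of ", p2)
          }
        }
        lines <- c(lines, "", "[Term]", paste0("id: ", ids[i]),
                   paste0("name: term_", sub("GO:", "", ids[i])),
                   paste0("namespace: ", ns),
                   paste0("is_a: ", p1, " ! parent"),
                   rel)
      }
      term_ids <- c(term_ids, ids)
      term_ns <- c(term_ns, rep(ns, k))
      level_of[[ns]] <- lvl
    }
    # alt_ids on the first n_alt terms
    if (spec$n_alt > 0L && length(term_ids)) {
      for (j in seq_len(min(spec$n_alt, length(term_ids)))) {
        tgt <- term_ids[j]
        alt <- sprintf("GO:%07d", 7000000L + j)
        at <- grep(paste0("^id: ", tgt, "$"), lines)
        lines <- append(lines, paste0("alt_id: ", alt), after = at)
      }
    }
    # obsolete stanzas
    for (j in seq_len(spec$n_obsolete)) {
      lines <- c(lines, "", "[Term]",
                 sprintf("id: GO:%07d", 8000000L + j),
                 sprintf("name: obsolete_term_%d", j),
                 "namespace: biological_process",
                 "is_obsolete: true")
    }
    # embedded consortium axioms
    if (!is.null(spec$axioms) && nrow(spec$axioms)) {
      ax <- spec$axioms
      for (j in seq_len(nrow(ax))) {
        gid <- ax$go_id[j]
        if (is.numeric(gid)) gid <- term_ids[as.integer(gid)]
        at <- grep(paste0("^id: ", gid, "$"), lines)
        if (length(at) == 0L) stop("axiom references unknown term: ", gid)
        tag <- if (ax$relation[j] == "never_in") "never_in_taxon"
               else "only_in_taxon"
        lines <- append(lines, sprintf("relationship: %s NCBITaxon:%d",
                                       tag, ax$taxon_id[j]), after = at)
      }
    }
    writeLines(lines, path)
  })
  g <- load_ontology(path, fmt = "obo")
  attr(g, "path") <- path
  invisible(g)
}

#' Generate a synthetic NCBI-style taxonomy
#'
#' Writes `nodes.dmp`, `names.dmp`, `merged.dmp` in the taxdump dialect
#' plus a `refnodes.tsv` sidecar listing the designated reference nodes.
#' One clade is named "environmental samples" so corpus-cleaning
#' fixtures have a target; two merged redirects point stale ids at real
#' leaves.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if absent).
#' @return The loaded `taxonomy_tree` with attributes `dir`,
#'   `ref_nodes` (integer vector), `env_leaf`, `merged_old` and
#'   `species` (leaf taxids suitable for annotation).
#' @export
make_taxonomy <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- with_fixture_rng(spec$seed + 23L, {
    n <- spec$n_taxa
    parent <- integer(n); parent[1L] <- 1L
    for (i in 2L:n) {
      # bias toward shallow ids keeps the tree broad
      w <- 1 / seq_len(i - 1L)
      parent[i] <- sample(seq_len(i - 1L), 1L, prob = w)
    }
    # environmental-samples clade: node n+1 under root, leaf n+2
    env_node <- n + 1L; env_leaf <- n + 2L
    taxid <- c(seq_len(n), env_node, env_leaf)
    parent <- c(parent, 1L, env_node)
    has_child <- taxid %in% parent[taxid != parent]
    rank <- ifelse(!has_child, "species",
                   ifelse(taxid == 1L, "no rank", "clade"))
    name <- paste0("taxon_", taxid)
    name[taxid == 1L] <- "root"
    name[taxid == env_node] <- "environmental samples"
    name[taxid == env_leaf] <- "uncultured organism"

    internal <- taxid[has_child & taxid != 1L & taxid != env_node]
    n_ref <- min(spec$n_ref, length(internal))
    ref_nodes <- if (n_ref > 0L) {
      sort(sample1(internal, n_ref))
    } else integer()

    leaves <- taxid[!has_child & taxid != env_leaf]
    merged_old <- c(900001L, 900002L)
    merged_new <- leaves[c(1L, min(2L, length(leaves)))]

    nodes_lines <- sprintf("%d\t|\t%d\t|\t%s\t|", taxid, parent, rank)
    names_lines <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                           taxid, name)
    # one synonym-only extra class line for flavour
    names_lines <- c(names_lines,
                     sprintf("%d\t|\t%s\t|\t\t|\tsynonym\t|",
                             taxid[2L], "some synonym"))
    merged_lines <- sprintf("%d\t|\t%d\t|", merged_old, merged_new)
    writeLines(nodes_lines, file.path(dir, "nodes.dmp"))
    writeLines(names_lines, file.path(dir, "names.dmp"))
    writeLines(merged_lines, file.path(dir, "merged.dmp"))
    utils::write.table(
      data.frame(taxid = ref_nodes,
                 label = rep("reliable", length(ref_nodes))),
      file.path(dir, "refnodes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(ref_nodes = ref_nodes, env_leaf = env_leaf,
         merged_old = merged_old, species = leaves)
  })
  t <- load_taxonomy(file.path(dir, "nodes.dmp"),
                     file.path(dir, "names.dmp"),
                     file.path(dir, "merged.dmp"))
  attr(t, "dir") <- dir
  attr(t, "ref_nodes") <- out$ref_nodes
  attr(t, "env_leaf") <- out$env_leaf
  attr(t, "merged_old") <- out$merged_old
  attr(t, "species") <- out$species
  invisible(t)
}

# ---- naive traversals used only by the generator/manifest oracle ----

naive_go_up <- function(parents, id) {
  out <- id
  for (p in parents[[id]]) out <- c(out, naive_go_up(parents, p))
  unique(out)
}

naive_tax_lineage <- function(parent_map, x) {
  out <- integer()
  cur <- x
  repeat {
    out <- c(out, cur)
    p <- parent_map[[as.character(cur)]]
    if (is.null(p) || p == cur) break
    cur <- p
  }
  out
}

#' Generate a synthetic GAF corpus with a planted-truth manifest
#'
#' Writes a GAF 2.2 file realizing a random annotation plan over the
#' fixture ontology and taxonomy, spiked with every category of dirty
#' line the cleaning step must remove, and a manifest TSV listing, for
#' every (reference node, GO term) pair, whether the constraint engine
#' must emit (`emit`) or must not emit (`suppress`) a `never_in` under
#' the spec's threshold — computed here by naive nested loops over the
#' written lines, independent of the pipeline code.
#'
#' @param spec A [fixture_spec()].
#' @param g Fixture `ontology_graph` from [make_ontology()].
#' @param t Fixture `taxonomy_tree` from [make_taxonomy()].
#' @param gaf_path Output GAF path.
#' @param manifest_path Output manifest TSV path.
#' @return Invisibly, a list with `manifest` (data.frame `ref_node`,
#'   `go_id`, `expected`), `planted` (data.frame of planted exclusion
#'   patterns), and `n_lines_written`.
#' @export
make_gaf <- function(spec, g, t, gaf_path, manifest_path) {
  res <- with_fixture_rng(spec$seed + 37L, {
    ref_nodes <- attr(t, "ref_nodes")
    species <- attr(t, "species")
    live_terms <- g$ids[!g$obsolete & !(g$ids %in% unname(g$roots))]

    # naive adjacency copies for the oracle
    parents <- g$parents
    parent_map <- as.list(t$parent)

    # planted exclusions: (ref node, term) pairs whose clade gets no
    # annotation to the term or its GO descendants
    planted <- data.frame(ref_node = integer(), go_id = character())
    if (spec$n_planted > 0L && length(ref_nodes) && length(live_terms)) {
      for (k in seq_len(spec$n_planted)) {
        planted <- rbind(planted, data.frame(
          ref_node = sample1(ref_nodes),
          go_id = sample1(live_terms)))
      }
      planted <- unique(planted)
    }
    # forbidden (taxon, term) pairs implied by the planted patterns
    forbidden <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(planted))) {
      clade <- naive_subtree(parent_map, t$taxids, planted$ref_node[k])
      down <- naive_go_down(parents, live_terms, planted$go_id[k])
      for (tx in intersect(clade, species)) {
        forbidden[[as.character(tx)]] <-
          c(forbidden[[as.character(tx)]], down)
      }
    }

    evid <- c("IEA", "IBA", "EXP", "ISS")
    # zipf-ish weight over terms so a handful clear the threshold
    wt <- 1 / rank(stats::runif(length(live_terms)))^0.9
    rows <- vector("list", spec$n_lines)
    for (i in seq_len(spec$n_lines)) {
      repeat {
        tx <- sample1(species)
        go <- sample1(live_terms, prob = wt)
        bad <- forbidden[[as.character(tx)]]
        if (is.null(bad) || !(go %in% bad)) break
      }
      rows[[i]] <- gaf_line(sprintf("P%05d", sample.int(200L, 1L)),
                            go, tx, sample1(evid))
    }
    lines <- unlist(rows)

    # dirty lines, each targeting exactly one cleaning rule
    nz <- spec$noise
    pick_go <- function() sample1(live_terms)
    pick_tx <- function() sample1(species)
    dirty <- c(
      vapply(seq_len(nz$nd %||% 0L), function(i)
        gaf_line("PND", pick_go(), pick_tx(), "ND"), character(1)),
      vapply(seq_len(nz$not %||% 0L), function(i)
        gaf_line("PNOT", pick_go(), pick_tx(), "IEA",
                 qualifier = "NOT|involved_in"), character(1)),
      vapply(seq_len(nz$root %||% 0L), function(i)
        gaf_line("PROOT", sample1(unname(g$roots)), pick_tx(), "IEA"),
        character(1)),
      vapply(seq_len(nz$rnacentral %||% 0L), function(i)
        gaf_line("PRNA", pick_go(), pick_tx(), "IEA",
                 db = "RNAcentral"), character(1)),
      vapply(seq_len(nz$env %||% 0L), function(i)
        gaf_line("PENV", pick_go(), attr(t, "env_leaf"), "IEA"),
        character(1)),
      vapply(seq_len(nz$unknown_taxon %||% 0L), function(i)
        gaf_line("PUNK", pick_go(), 999999L, "IEA"), character(1)),
      vapply(seq_len(nz$obsolete %||% 0L), function(i)
        gaf_line("POBS", "GO:8000001", pick_tx(), "IEA"), character(1)),
      rep("UniProtKB\tPMAL\ttruncated", nz$malformed %||% 0L)
    )
    all_lines <- c("!gaf-version: 2.2", lines, dirty)
    writeLines(all_lines, gaf_path)

    # ---- brute-force manifest over the written signal lines ----
    # naive cleaning mirror: dirty categories above are re-detected by
    # rule, not by provenance
    clean <- list()
    for (ln in c(lines, dirty)) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 15L) next
      if (f[7L] == "ND") next
      if ("NOT" %in% strsplit(f[4L], "|", fixed = TRUE)[[1L]]) next
      go <- f[5L]
      if (go %in% unname(GO_ROOTS)) next
      if (f[1L] == "RNAcentral" || f[15L] == "RNAcentral") next
      if (!(go %in% live_terms)) next
      tx <- as.integer(sub("^taxon:", "", sub("\\|.*$", "", f[13L])))
      if (!(as.character(tx) %in% names(parent_map))) next
      lin <- naive_tax_lineage(parent_map, tx)
      if (any(grepl("environmental sample",
                    t$sci_name[as.character(lin)],
                    ignore.case = TRUE))) next
      clean[[length(clean) + 1L]] <- list(go = go, tx = tx)
    }
    # cumulative frequencies by nested loops
    glob <- stats::setNames(integer(length(g$ids)), g$ids)
    refc <- lapply(ref_nodes, function(r)
      stats::setNames(integer(length(g$ids)), g$ids))
    names(refc) <- as.character(ref_nodes)
    for (a in clean) {
      up <- naive_go_up(parents, a$go)
      glob[up] <- glob[up] + 1L
      lin <- naive_tax_lineage(parent_map, a$tx)
      # an annotation counts for every reference node on the organism's
      # lineage, so nested reference nodes accumulate to their ancestors
      for (r in as.character(lin[lin %in% ref_nodes])) {
        refc[[r]][up] <- refc[[r]][up] + 1L
      }
    }
    manifest <- do.call(rbind, lapply(as.character(ref_nodes),
                                      function(r) {
      emit <- g$ids[glob >= spec$threshold & refc[[r]] == 0L &
                      !g$obsolete]
      near <- g$ids[(glob >= spec$threshold & refc[[r]] > 0L) |
                      (glob > 0L & glob < spec$threshold &
                         refc[[r]] == 0L)]
      near <- setdiff(near[!g$obsolete[near]], emit)
      rbind(
        if (length(emit)) data.frame(ref_node = as.integer(r),
                                     go_id = emit, expected = "emit"),
        if (length(near)) data.frame(ref_node = as.integer(r),
                                     go_id = near, expected = "suppress"))
    }))
    if (is.null(manifest)) {
      manifest <- data.frame(ref_node = integer(), go_id = character(),
                             expected = character())
    }
    rownames(manifest) <- NULL
    list(manifest = manifest, planted = planted,
         n_lines_written = length(all_lines) - 1L)
  })
  utils::write.table(res$manifest, manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(res)
}

naive_subtree <- function(parent_map, taxids, root) {
  taxids[vapply(taxids, function(x)
    root %in% naive_tax_lineage(parent_map, x), logical(1))]
}

naive_go_down <- function(parents, ids, top) {
  ids[vapply(ids, function(x) top %in% naive_go_up(parents, x),
             logical(1))]
}

gaf_line <- function(obj, go, taxon, evidence, qualifier = "involved_in",
                     db = "UniProtKB") {
  paste(db, obj, obj, qualifier, go, "PMID:1", evidence, "",
        "P", "", "", "protein", paste0("taxon:", taxon),
        "20240101", "UniProt", "", "", sep = "\t")
}

#' Generate a complete fixture bundle
#'
#' Convenience wrapper running [make_ontology()], [make_taxonomy()] and
#' [make_gaf()] into one directory.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return List with `ontology`, `taxonomy`, `gaf` (paths), the loaded
#'   `g` and `t`, the `manifest` data.frame, `planted`, `ref_nodes`.
#' @export
make_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obo <- file.path(dir, "ontology.obo")
  g <- make_ontology(spec, obo)
  t <- make_taxonomy(spec, dir)
  gaf <- file.path(dir, "annotations.gaf")
  mf <- file.path(dir, "manifest.tsv")
  res <- make_gaf(spec, g, t, gaf, mf)
  list(ontology = obo, taxonomy_dir = dir, gaf = gaf,
       manifest_path = mf, refnodes_path = file.path(dir, "refnodes.tsv"),
       g = g, t = t, manifest = res$manifest, planted = res$planted,
       ref_nodes = attr(t, "ref_nodes"))
}
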