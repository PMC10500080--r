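# The three GO namespace roots (cellular_component, biological_process,
# molecular_function) in their canonical zero-padded form.
GO_ROOTS <- c(
  cellular_component = "GO:0005575",
  biological_process = "GO:0008150",
  molecular_function = "GO:0003674"
)

GO_NAMESPACES <- names(GO_ROOTS)

#' Gene Ontology DAG container
#'
#' An `ontology_graph` holds the GO term table, the directed parent links
#' split into propagating (`is_a`, `part_of` by default) and
#' non-propagating (regulates-family) relations, the three namespace
#' roots, and any taxon-constraint axioms (`never_in_taxon` /
#' `only_in_taxon`) found in the source file.
#'
#' @param path Path to an ontology file.
#' @param fmt Dialect: `"obo"` (OBO 1.2/1.4 flat file) or `"owl"`
#'   (RDF/XML). Guessed from the file extension when missing.
#' @param propagating Character vector of relation labels that propagate
#'   annotations up the graph. Default `c("is_a", "part_of")`, the
#'   standard annotation-propagation pair.
#' @return An object of class `ontology_graph` with components `ids`,
#'   `name`, `namespace`, `obsolete` (all named by GO id), `alt` (map
#'   alt_id -> primary id), `parents` / `children` (named lists of
#'   propagating neighbours), `other_parents` (non-propagating edges),
#'   `roots`, and `axioms` (data.frame `go_id`, `relation`, `taxon_id`).
#' @export
load_ontology <- function(path, fmt = c("obo", "owl"),
                          propagating = c("is_a", "part_of")) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  if (missing(fmt)) {
    fmt <- if (grepl("\\.owl$", path, ignore.case = TRUE)) "owl" else "obo"
  }
  fmt <- match.arg(fmt)
  parsed <- if (fmt == "obo") parse_obo(path) else parse_owl(path)
  build_ontology_graph(parsed, propagating = propagating, source = path)
}

# Parse an OBO 1.2/1.4 flat file into a list of term records.
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (length(starts) == 0L) stop("format error: no stanzas found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  terms <- vector("list", length(starts))
  n <- 0L
  for (i in seq_along(starts)) {
    header <- lines[starts[i]]
    if (header != "[Term]") next
    body <- lines[(starts[i] + 1L):ends[i]]
    body <- body[nzchar(body)]
    kv <- regmatches(body, regexpr("^[^:]+", body))
    val <- sub("^[^:]+:\\s*", "", body)
    # strip trailing comments ( " ! ..." )
    val <- sub("\\s+!.*$", "", val)
    id <- val[kv == "id"][1L]
    if (is.na(id) || !grepl("^GO:\\d{7}$", id)) {
      stop("format error: stanza without a valid GO id near line ",
           starts[i], " ('", if (is.na(id)) "<missing>" else id, "')")
    }
    rels <- val[kv == "relationship"]
    rel_type <- sub("\\s.*$", "", rels)
    rel_tgt <- sub("^\\S+\\s+", "", rels)
    terms[[n <- n + 1L]] <- list(
      id = id,
      name = val[kv == "name"][1L],
      namespace = val[kv == "namespace"][1L],
      obsolete = isTRUE(any(val[kv == "is_obsolete"] == "true")),
      alt_ids = val[kv == "alt_id"],
      is_a = val[kv == "is_a"],
      rel_type = rel_type,
      rel_tgt = rel_tgt
    )
  }
  terms[seq_len(n)]
}

# Minimal RDF/XML (OWL) reader for GO-shaped content: owl:Class elements
# with rdfs:subClassOf links (plain resource = is_a; restriction on a
# property labelled part_of = part_of) and never_in_taxon/only_in_taxon
# annotation axioms referencing NCBITaxon ids.
parse_owl <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  classes <- xml2::xml_find_all(doc, ".//owl:Class[@rdf:about]", ns)
  uri2go <- function(x) {
    m <- regmatches(x, regexpr("GO_\\d{7}", x))
    if (length(m)) sub("_", ":", m) else NA_character_
  }
  terms <- lapply(classes, function(cl) {
    about <- xml2::xml_attr(cl, "about")
    id <- uri2go(about)
    if (is.na(id)) return(NULL)
    nm <- xml2::xml_text(xml2::xml_find_first(cl, "./rdfs:label", ns))
    nsp <- xml2::xml_text(xml2::xml_find_first(
      cl, "./oboInOwl:hasOBONamespace", ns))
    dep <- xml2::xml_find_first(cl, "./owl:deprecated", ns)
    obsolete <- !inherits(dep, "xml_missing") &&
      xml2::xml_text(dep) == "true"
    subs <- xml2::xml_find_all(cl, "./rdfs:subClassOf", ns)
    is_a <- character()
    rel_type <- character()
    rel_tgt <- character()
    for (s in subs) {
      res <- xml2::xml_attr(s, "resource")
      if (!is.na(res)) {
        tgt <- uri2go(res)
        if (!is.na(tgt)) is_a <- c(is_a, tgt)
        next
      }
      restr <- xml2::xml_find_first(s, "./owl:Restriction", ns)
      if (inherits(restr, "xml_missing")) next
      prop <- xml2::xml_attr(
        xml2::xml_find_first(restr, "./owl:onProperty", ns), "resource")
      filler <- xml2::xml_attr(
        xml2::xml_find_first(restr, "./owl:someValuesFrom", ns), "resource")
      if (is.na(prop) || is.na(filler)) next
      label <- sub("^.*[/#]", "", prop)
      if (grepl("never_in_taxon|only_in_taxon|NCBITaxon", filler) ||
          grepl("never_in_taxon|only_in_taxon", label)) {
        tax <- regmatches(filler, regexpr("NCBITaxon_\\d+", filler))
        if (length(tax)) {
          rel_type <- c(rel_type, sub("RO_0002161", "never_in_taxon", label))
          rel_tgt <- c(rel_tgt, sub("NCBITaxon_", "NCBITaxon:", tax))
          next
        }
      }
      tgt <- uri2go(filler)
      if (!is.na(tgt)) {
        rel_type <- c(rel_type, label)
        rel_tgt <- c(rel_tgt, tgt)
      }
    }
    alt <- xml2::xml_text(xml2::xml_find_all(
      cl, "./oboInOwl:hasAlternativeId", ns))
    list(id = id, name = nm, namespace = nsp,
         obsolete = obsolete, alt_ids = alt,
         is_a = is_a, rel_type = rel_type, rel_tgt = rel_tgt)
  })
  terms[!vapply(terms, is.null, logical(1))]
}

build_ontology_graph <- function(terms, propagating, source) {
  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("integrity error: duplicated term ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  nm <- vapply(terms, function(t) t$name %||% NA_character_, character(1))
  nsp <- vapply(terms, function(t) t$namespace %||% NA_character_,
                character(1))
  obsolete <- vapply(terms, `[[`, logical(1), "obsolete")
  names(nm) <- names(nsp) <- names(obsolete) <- ids

  # alt_id map
  alt_from <- unlist(lapply(terms, `[[`, "alt_ids"), use.names = FALSE)
  alt_to <- rep(ids, vapply(terms, function(t) length(t$alt_ids),
                            integer(1)))
  alt <- stats::setNames(alt_to, alt_from)

  parents <- stats::setNames(vector("list", length(ids)), ids)
  other_parents <- stats::setNames(vector("list", length(ids)), ids)
  ax_go <- character(); ax_rel <- character(); ax_tax <- integer()
  skipped_axioms <- 0L
  live_ids <- ids[!obsolete]
  for (t in terms) {
    if (t$obsolete) next  # obsolete terms participate in no edges
    p <- t$is_a[t$is_a %in% live_ids]
    o <- character()
    for (j in seq_along(t$rel_type)) {
      rt <- t$rel_type[j]; tg <- t$rel_tgt[j]
      if (grepl("never_in_taxon|only_in_taxon", rt)) {
        taxm <- regmatches(tg, regexpr("NCBITaxon:\\d+", tg))
        if (length(taxm)) {
          ax_go <- c(ax_go, t$id)
          ax_rel <- c(ax_rel,
                      if (grepl("never_in_taxon", rt)) "never_in"
                      else "only_in")
          ax_tax <- c(ax_tax, as.integer(sub("NCBITaxon:", "", taxm)))
        } else skipped_axioms <- skipped_axioms + 1L
        next
      }
      if (!tg %in% live_ids) next
      if (rt %in% propagating) p <- c(p, tg) else o <- c(o, tg)
    }
    parents[[t$id]] <- unique(p)
    other_parents[[t$id]] <- unique(o)
  }

  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }

  roots <- GO_ROOTS[GO_ROOTS %in% ids]
  g <- structure(list(
    ids = ids, name = nm, namespace = nsp, obsolete = obsolete,
    alt = alt, parents = parents, children = children,
    other_parents = other_parents, roots = roots,
    axioms = data.frame(go_id = ax_go, relation = ax_rel,
                        taxon_id = ax_tax, stringsAsFactors = FALSE),
    skipped_axioms = skipped_axioms,
    propagating = propagating, source = source,
    cache = new.env(parent = emptyenv())
  ), class = "ontology_graph")
  check_acyclic(g)
  g
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# Kahn toposort over propagating edges; cycles raise an integrity error.
check_acyclic <- function(g) {
  live <- g$ids[!g$obsolete[g$ids]]
  indeg <- vapply(g$parents[live], length, integer(1))
  queue <- live[indeg == 0L]
  seen <- 0L
  indeg <- stats::setNames(indeg, live)
  while (length(queue)) {
    x <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in g$children[[x]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(live)) {
    stop("integrity error: cycle detected in the propagating relation ",
         "closure (", length(live) - seen, " terms unreachable from roots)")
  }
  invisible(TRUE)
}

#' Resolve a GO id (possibly an alt_id) to its primary id
#'
#' @param g An `ontology_graph`.
#' @param go_id GO identifier(s).
#' @return Primary id(s); `NA` where unknown.
#' @export
resolve_go_id <- function(g, go_id) {
  out <- ifelse(go_id %in% g$ids, go_id,
                unname(g$alt[go_id]))
  out
}

#' Term metadata lookup
#'
#' @param g An `ontology_graph`.
#' @param go_id A GO identifier (primary or alt_id).
#' @return A list with `id`, `name`, `namespace`, `obsolete`, resolved to
#'   the primary term.
#' @export
term_info <- function(g, go_id) {
  id <- resolve_go_id(g, go_id)
  if (is.na(id)) stop("unknown GO id: ", go_id)
  list(id = id, name = unname(g$name[id]),
       namespace = unname(g$namespace[id]),
       obsolete = unname(g$obsolete[id]))
}

closure_walk <- function(g, go_id, link, cache_prefix) {
  key <- paste0(cache_prefix, go_id)
  hit <- g$cache[[key]]
  if (!is.null(hit)) return(hit)
  seen <- character()
  frontier <- g[[link]][[go_id]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(g[[link]][new], use.names = FALSE))
  }
  g$cache[[key]] <- seen
  seen
}

#' Descendants of a GO term
#'
#' Transitive closure under the propagating relations, excluding the term
#' itself.
#'
#' @param g An `ontology_graph`.
#' @param go_id GO identifier (primary form).
#' @return Character vector of descendant GO ids (possibly empty).
#' @export
go_descendants <- function(g, go_id) {
  if (!go_id %in% g$ids) stop("unknown GO id: ", go_id)
  if (g$obsolete[[go_id]]) stop("term is obsolete: ", go_id)
  closure_walk(g, go_id, "children", "d.")
}

#' Ancestors of a GO term
#'
#' Transitive closure under the propagating relations, excluding the term
#' itself.
#'
#' @inheritParams go_descendants
#' @return Character vector of ancestor GO ids.
#' @export
go_ancestors <- function(g, go_id) {
  if (!go_id %in% g$ids) stop("unknown GO id: ", go_id)
  closure_walk(g, go_id, "parents", "a.")
}

#' Extract consortium taxon-constraint axioms
#'
#' Returns the `never_in_taxon` / `only_in_taxon` axioms embedded in the
#' ontology file, one row per axiom, ordered by (go_id, relation).
#' Axioms referencing GO ids absent from the graph were dropped at load
#' time with a counted warning (`g$skipped_axioms`).
#'
#' @param g An `ontology_graph`.
#' @return A data.frame with columns `go_id`, `relation`
#'   (`"never_in"`/`"only_in"`), `taxon_id`.
#' @export
extract_goc_axioms <- function(g) {
  ax <- g$axioms
  if (g$skipped_axioms > 0L) {
    warning(g$skipped_axioms,
            " taxon-constraint axiom(s) skipped (unparsable taxon id)")
  }
  ax[order(ax$go_id, ax$relation), , drop = FALSE]
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", length(x$ids), " terms (",
      sum(x$obsolete), " obsolete), ", length(x$roots), " roots, ",
      nrow(x$axioms), " taxon-constraint axioms\n", sep = "")
  invisible(x)
}
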