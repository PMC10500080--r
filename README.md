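# gotaxcon — taxon-based Gene Ontology constraints from annotation corpora

GO annotations are species-agnostic, but functions are not: annotation
databases contain proteins of chloroplast-free parasites annotated with
"chloroplast thylakoid", and automatic function predictors routinely
transfer photosynthesis terms onto bacteria that have none. `gotaxcon`
derives **taxon constraints** — per-clade lists of forbidden GO terms
("never_in") — directly from a GO annotation corpus, merges them with
the Gene Ontology Consortium's curated `never_in`/`only_in` axioms and
with user-written manual overrides under a strict priority scheme, and
puts them to work three ways: filtering predicted annotations, auditing
databases for violations, and scoring the effect on predictions with
the CAFA species-centric metrics.

It is written for computational biologists who work with GAF annotation
files, the NCBI taxonomy, and GO in OBO/OWL form.

## The core rule

For each *reference taxonomic node* (a taxonomy node pooling the
annotations of every organism beneath it), and for each GO term `g`
with corpus-wide cumulative frequency — annotations to `g` or any GO
descendant of `g` — of at least a threshold (default **500**):

> if the cumulative frequency of `g` inside the reference node's
> subtree is **zero**, emit `never_in(node, g)`: neither `g` nor any of
> its GO descendants may annotate any species of that clade.

Merging applies priority `manual > consortium > automatic`; consortium
`only_in(g, T)` axioms convert to `never_in` everywhere outside
`subtree(T)`; a manual `allow` punches a clade-shaped hole in any
lower-priority prohibition. Evaluation pools each species' predicted
terms into one max-scored set and sweeps thresholds for
`F_max`, `wF_max` (information-content-weighted) and
`S_min = min √(ru² + mi²)`.

See `vignettes/taxon-constraints-methods.Rmd` for the full model,
parameter meanings, and design choices.

## Worked example

Everything below runs offline: the fixture generator writes a synthetic
ontology, taxonomy and GAF corpus from one seed, then the pipeline
derives constraints from those files.

```r
library(gotaxcon)

dir <- tempfile()
b <- make_fixture_bundle(fixture_spec(seed = 2L), dir)

cfg <- pipeline_config(
  ontology = b$ontology, gaf = b$gaf, taxdump_dir = dir,
  reference_nodes = b$refnodes_path,
  min_global_frequency = 50L,          # corpus-scale default is 500
  output_dir = file.path(dir, "out"))
res <- cmd_generate(cfg)

print(res$report)
#> <cleaning_report> in: 721  out: 700
#>   nd_evidence: 4
#>   not_qualifier: 4
#>   root_term: 3
#>   rnacentral: 3
#>   environmental_sample: 3
#>   obsolete_term: 2
#>   unknown_taxon: 2
```

Of the 721 GAF lines, 21 were removed — 4 with the `ND` evidence code,
4 with a `NOT` qualifier, 3 annotating a namespace root, and so on; the
700 survivors feed the frequency engine. One planted absence cleared
the threshold:

```r
res$cs$records[res$cs$records$source == "automatic",
               c("taxon_id", "go_id", "relation", "reference_node")]
#>   taxon_id      go_id relation reference_node
#> 1        7 GO:0000114 never_in              7
```

`GO:0000114` is used at least 50 times corpus-wide but never inside
reference node 7's clade, so it is forbidden there. Querying any
species of that clade expands the compact record over the GO graph
(the term plus its seven descendants):

```r
cmd_query(res$paths$constraints, 19L, b$g, b$t)
#>   taxon_id taxon_name      go_id      go_name          namespace
#> 1       19   taxon_19 GO:0000114 term_0000114 biological_process
#> 2       19   taxon_19 GO:0000117 term_0000117 biological_process
#> 3       19   taxon_19 GO:0000118 term_0000118 biological_process
#> ...
```

Auditing the corpus against its own constraints reports zero
violations — by construction, a term annotated anywhere in a clade is
never forbidden for it:

```r
nrow(cmd_audit(b$gaf, res$paths$constraints, b$g, b$t))
#> [1] 0
```

A shell wrapper with `generate` / `query` / `audit` / `evaluate` /
`fixtures` subcommands lives in `inst/scripts/gotaxcon.R`:

```sh
Rscript inst/scripts/gotaxcon.R generate --config pipeline.cfg
Rscript inst/scripts/gotaxcon.R query --config pipeline.cfg \
    --constraints out/constraints.tsv --taxon "taxon_19"
```

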