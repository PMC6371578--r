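# Shared synthetic cohorts, generated once per test run and cached.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, force(expr), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

# small cohort for fast structural checks
small_cohort <- function() cached("small", generate_cohort(
  sim_config(n_case = 20, n_control = 20, n_genes = 150, probes_per_region = 2,
             n_intergenic = 100, n_hypo_up = 10, n_diff_intergenic = 15,
             seed = 42)))

# the planted study-scale cohort (200/200, 85 hypo-up, default effects)
planted_cohort <- function() cached("planted", generate_cohort(sim_config(seed = 1)))

# per-region + ALL aggregates of the planted cohort
planted_levels <- function() cached("planted_levels", {
  co <- planted_cohort()
  sel <- c(REGION_LABELS, "ALL")
  setNames(lapply(sel, function(r)
    aggregate_region(co$methylation, co$annotation, r)), sel)
})

hypo_up_truth <- function(cohort) {
  tg <- cohort$truth$genes
  tg$feature_id[tg$class == "hypo-up"]
}

# tiny annotation fixture written to a temp file
write_fixture_annotation <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("probe_id\tchr\tposition\tgene_names\tregion_groups\tenhancer",
               lines), path)
  path
}
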