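# shared four-study fixture and pipeline run, memoized across test files
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(seed = 1L) {
  key <- paste0("fix", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_four_study_fixture(seed = seed)
  .fixture_cache[[key]]
}

fixture_config <- function(fix, seed = 1L, out_dir = NULL) {
  analysis_config(
    datasets = list(
      list(name = "K", expression = fix$expression$K, genotypes = "CEU",
           representative = "group"),
      list(name = "S", expression = fix$expression$S, genotypes = "CEU",
           representative = "reference:K"),
      list(name = "C", expression = fix$expression$C, genotypes = "CEU",
           representative = "auto"),
      list(name = "D", expression = fix$expression$D, genotypes = "D",
           representative = "probe:D01")),
    genotypes = fix$genotypes,
    functional_ids = fix$truth$functional_ids,
    tag_ids = fix$truth$tag_ids,
    haplotypes = fix$truth$pool,
    seed = seed, out_dir = out_dir)
}

get_fixture_bundle <- function(seed = 1L) {
  key <- paste0("bundle", seed)
  if (is.null(.fixture_cache[[key]])) {
    fix <- get_fixture(seed)
    .fixture_cache[[key]] <- suppressMessages(
      run_pipeline(fixture_config(fix, seed)))
  }
  .fixture_cache[[key]]
}

# the fixture's 6-haplotype/8-tag pool, for phasing tests
fixture_pool_for_tests <- function() get_fixture(1L)$truth$pool
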