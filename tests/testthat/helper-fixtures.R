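## Shared fixtures: tiny simulation worlds built in code.

## a small, fast configuration used across module tests
tiny_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(seed = seed, genome_length = 40000, n_background_alus = 4,
         n_novel_insertions = 5, truncation_prob = 0, divergence = 0,
         conversion_rate = 1, error_rate = 0, reads_per_locus = 3),
    list(...))
  do.call(sim_config, args)
}

tiny_world <- function(seed = 11, ...) {
  cfg <- tiny_config(seed, ...)
  ref <- make_reference(cfg)
  sim <- simulate_tprt_insertion(ref, cfg)
  list(cfg = cfg, ref = ref, sim = sim)
}

## plain-R reverse complement, independent of the package's helper
rc_chr <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## path to a bundled fixture
fixture <- function(name) system.file("extdata", name, package = "alutrace")
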