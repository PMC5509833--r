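# Shared fixtures, all built in code at test time.

# Toy tariff: any-problem constant 0.10, mobility level 2 decrement 0.05.
toy_tariff_file <- function() {
  path <- tempfile(fileext = ".csv")
  writeLines(c("term,dimension,level,value",
               "constant,,,0.10",
               "decrement,1,2,0.05"), path)
  path
}

synthetic_belgian_tariff <- function() {
  read_tariff(system.file("extdata", "tariff_belgium_synthetic.csv",
                          package = "qolnorm"))
}

# Small complete cohort with the nominal index range attached as a spec,
# so fitted coefficients are comparable to the generating truth.
make_cohort <- function(n, seed, cfg = NULL) {
  if (is.null(cfg)) cfg <- truth_config(n = n, seed = seed)
  d <- generate_cohort(cfg)
  spec <- transform_spec(nrow(d), cfg$index_range[1], cfg$index_range[2])
  d$vas_t <- transform_vas(d$vas, spec)
  d$eq5d_t <- transform_eq5d(d$eq5d_index, spec)
  attr(d, "spec") <- spec
  d
}

# Cohort plus the numeric truth-design columns, for fits whose coefficient
# names line up exactly with the generating coefficients.
make_truth_frame <- function(n, seed, cfg = NULL) {
  d <- make_cohort(n, seed, cfg)
  td <- as.data.frame(truth_design(d))
  td$vas_t <- d$vas_t
  td$eq5d_t <- d$eq5d_t
  attr(td, "spec") <- attr(d, "spec")
  td
}
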