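# small in-code fixtures shared across test files

three_site_transect <- function(velocity = 5) {
  build_transect(data.frame(
    site_id = c("a", "b", "c"),
    rkm = c(120, 110, 100),
    velocity = velocity,
    stringsAsFactors = FALSE
  ))
}

# tiny ASV table: explicit counts, one sample per site
toy_asv_table <- function(counts, site_ids = NULL) {
  if (is.null(site_ids)) site_ids <- colnames(counts)
  asv_table(counts,
            data.frame(sample_id = colnames(counts), site_id = site_ids,
                       stringsAsFactors = FALSE))
}

# brute-force Sorensen/Simpson partition from incidence counts
partition_oracle <- function(a, b, c) {
  sim <- if (a + min(b, c) == 0) 0 else min(b, c) / (a + min(b, c))
  sor <- if (2 * a + b + c == 0) 0 else (b + c) / (2 * a + b + c)
  list(beta_sim = sim, beta_sor = sor, beta_nes = sor - sim)
}

# build presence vectors realizing incidence counts (a shared, b, c unique)
presence_pair <- function(a, b, c) {
  n <- a + b + c
  x <- c(rep(TRUE, a), rep(TRUE, b), rep(FALSE, c))
  y <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c))
  list(x = x, y = y)
}
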