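# the synthetic validation cohort is expensive (~1 min); build it once and
# share across test files
.cohort_cache <- new.env(parent = emptyenv())

cohort_fixture <- function() {
  if (is.null(.cohort_cache$sim)) {
    .cohort_cache$sim <- simulate_validation_cohort(sim_config(seed = 101L))
    .cohort_cache$res <- run_validation_pipeline(.cohort_cache$sim)
  }
  list(sim = .cohort_cache$sim, res = .cohort_cache$res)
}

# brute-force per-base footprint of closed regions
brute_force_bp <- function(regions) {
  if (!nrow(regions)) return(0L)
  length(unique(unlist(lapply(seq_len(nrow(regions)), function(i)
    paste(regions$chrom[i], regions$start[i]:regions$stop[i])))))
}

# brute-force binomial tail by enumerating all 2^n per-read outcomes
enum_binom_le_k <- function(n, p, k) {
  if (n == 0) return(1)
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  cnt <- rowSums(grid)
  prob <- apply(grid, 1, function(z) prod(ifelse(z == 1, p, 1 - p)))
  sum(prob[cnt <= k])
}
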