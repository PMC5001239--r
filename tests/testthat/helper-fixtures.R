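## Shared fixtures, all built in code.

toy_maf <- function() {
  data.frame(
    sample_id = c("S1", "S2", "S2", "S4", "S5"),
    gene_symbol = c("PBRM1", "PBRM1", "VHL", "PBRM1", "SETD2"),
    variant_class = c("nonsense", "nonsense", "missense", "missense",
                      "nonsense"),
    stringsAsFactors = FALSE)
}

toy_samples <- function() paste0("S", 1:5)

## Small synthetic cohort for fast end-to-end unit tests.
small_config <- function(seed = 7, ...) {
  sim_config(n_genes = 400, n_probes = 600, n_mirnas = 60,
             n_de_genes = 40, n_dm_probes = 40, n_de_mirnas = 10,
             n_other = 4, seed = seed, ...)
}

## Independent two-sided binomial p-value by probability ordering, from
## exact rational binomial masses (choose / 2^t).
binom_smallp_oracle <- function(a, t) {
  mass <- choose(t, 0:t) / 2^t
  sum(mass[mass <= mass[a + 1L] * (1 + 1e-12)])
}

## Independent SAM d for one split, mirroring the definition by hand.
sam_d_oracle <- function(x_case, x_ctrl, s0) {
  n1 <- length(x_case); n2 <- length(x_ctrl)
  sp <- (sum((x_case - mean(x_case))^2) + sum((x_ctrl - mean(x_ctrl))^2)) /
    (n1 + n2 - 2)
  s <- sqrt((1 / n1 + 1 / n2) * sp)
  (mean(x_case) - mean(x_ctrl)) / (s + s0)
}
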