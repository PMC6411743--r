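# shared fixture builders: everything is generated in code at test time

# a minimal valid 2D metadata table: 2 temperatures x 5 concentrations,
# one plex, one replicate
toy_2d_meta <- function(temps = c(42, 44.1), concs = c(0, 0.005, 0.05, 0.5, 2)) {
  g <- expand.grid(temperature = temps, concentration_mM = concs,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$temperature, g$concentration_mM), ]
  data.frame(
    sample_id = sprintf("S%02d", seq_len(nrow(g))),
    replicate = 1L,
    temperature = g$temperature,
    concentration_mM = g$concentration_mM,
    detergent = "NP40",
    tmt_plex = "p1",
    tmt_label = c("126", "127L", "127H", "128L", "128H",
                  "129L", "129H", "130L", "130H", "131"),
    stringsAsFactors = FALSE
  )
}

# wide quant table matching toy_2d_meta, 3 proteins, optional qupm column
toy_wide_quant <- function(meta, n_proteins = 3, qupm = c(2, 3, 9)) {
  set.seed(99)
  m <- matrix(rlnorm(n_proteins * nrow(meta), log(1e6), 0.2),
              n_proteins, nrow(meta), dimnames = list(NULL, meta$sample_id))
  data.frame(protein_id = sprintf("P%d", seq_len(n_proteins)),
             qupm = qupm, m, check.names = FALSE, stringsAsFactors = FALSE)
}

write_toy_tables <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  meta <- toy_2d_meta()
  wide <- toy_wide_quant(meta)
  qp <- file.path(dir, "quant.tsv"); mp <- file.path(dir, "meta.tsv")
  write.table(wide, qp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(quant = qp, meta = mp, dir = dir)
}

# small 2D simulation + analysis config used across tests
quick_2d_sim <- function(n = 40, seed = 1, noise_cv = 0.05, ...) {
  simulate_2dtpp(sim_config("TPP_2D", n_proteins = n, seed = seed,
                            noise_cv = noise_cv, ...))
}

quick_cfg <- function(...) analysis_config(n_permutations = 10, seed = 1, ...)
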