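# shared fixture builder: paired matrices written as TSV, optionally with
# induced confounder triplets so significant results are guaranteed
write_fixture_pair <- function(dir, seed = 91, induce = FALSE) {
  sim <- simulate_latent_datasets(n_samples = if (induce) 60 else 20,
                                  p_linker = 4, m_vertex = 6, seed = seed)
  if (induce) {
    ind <- induce_true_triplets(sim$linker, sim$vertex, n_true = 2, t = 0.6,
                                seed = seed + 1)
    sim$vertex <- ind$vertex
  }
  vp <- file.path(dir, "vertex.tsv")
  lp <- file.path(dir, "linker.tsv")
  write_omics_matrix(sim$vertex, vp)
  write_omics_matrix(sim$linker, lp)
  list(vertex = vp, linker = lp, sim = sim)
}
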