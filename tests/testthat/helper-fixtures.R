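# Shared small fixtures, generated in code.

tiny_refdb <- function(seed = 1, ...) {
  build_reference_db(seed = seed, ...)
}

# A small but complete synthetic run: returns list(refdb, communities, sim).
small_world <- function(seed = 101, reads_per_site = 600, error_rate = 0,
                        chimera_rate = 0, offtarget_fraction = 0.02, ...) {
  refdb <- build_reference_db(seed = seed)
  comm <- simulate_communities(refdb, reads_per_site = reads_per_site,
                               seed = seed + 1)
  sim <- simulate_reads(comm, refdb, error_rate = error_rate,
                        chimera_rate = chimera_rate,
                        offtarget_fraction = offtarget_fraction,
                        seed = seed + 2, ...)
  list(refdb = refdb, communities = comm, sim = sim)
}

# Species label of a genotype name ("..._spX_gtY" -> "..._spX").
species_of <- function(genotype) sub("_gt[0-9]+$", "", genotype)
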