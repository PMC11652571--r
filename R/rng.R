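# Seed plumbing: a single master seed spawns reproducible per-trial integer
# seeds so every trial's melodies can be regenerated in isolation.

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Deterministic stream seeds below 2^31; exact in double arithmetic.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 69621 + 1) %%
               2147483647)
}
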