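# Independent mass oracle: builds PE masses by molecular bookkeeping
# (glycerophosphoethanolamine backbone + chains - condensation water)
# instead of the package's closed-form element counts.
oracle_mass <- local({
  m <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
         O = 15.9949146196, P = 30.97376163)
  mass_of <- function(counts) sum(m[names(counts)] * counts)
  water <- c(C = 0, H = 2, N = 0, O = 1, P = 0)
  gpe <- c(C = 5, H = 14, N = 1, O = 6, P = 1)  # glycerophosphoethanolamine
  fatty_acid <- function(c, d) c(C = c, H = 2 * c - 2 * d, N = 0, O = 2, P = 0)
  fatty_alcohol <- function(c, d) c(C = c, H = 2 * c + 2 - 2 * d, N = 0,
                                    O = 1, P = 0)
  function(chain1_c, chain1_d, chain2_c, chain2_d,
           sn1 = c("acyl", "alkyl", "alkenyl")) {
    sn1 <- match.arg(sn1)
    # alkenyl = fatty alcohol with one extra (Delta-1) double bond
    sn1_part <- switch(sn1,
      acyl = fatty_acid(chain1_c, chain1_d),
      alkyl = fatty_alcohol(chain1_c, chain1_d),
      alkenyl = fatty_alcohol(chain1_c, chain1_d + 1))
    total <- gpe + sn1_part + fatty_acid(chain2_c, chain2_d) - 2 * water
    mass_of(total)
  }
})

oracle_mz_deprotonated <- function(...) {
  oracle_mass(...) - (1.00782503207 - 0.00054857990907)
}
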