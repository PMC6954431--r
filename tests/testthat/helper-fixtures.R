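# Shared fixtures: idealized nucleotides and a small dinucleotide chain,
# built in code so every test works from first principles.

make_dinucleotide <- function() {
  build_chain(n = 2, chain = "A", free_5prime = TRUE,
              chi = c(-120, 45), gamma = c(60, -170),
              nu0 = c(-25, 1), nu1 = c(37, -23),
              sugar_type = c("deoxyribose", "ribose"),
              base_type = c("purine", "pyrimidine"))
}

# single residue with two alternative conformations (A/B) of the whole sugar
make_altloc_residue <- function() {
  a <- build_nucleotide(chi = -120, gamma = 60, altloc = "A", occupancy = 0.6)
  b <- build_nucleotide(chi = -95, gamma = 55, altloc = "B", occupancy = 0.4)
  rbind(a, b)
}

# tiny protein-like file with no sugars
make_protein_atoms <- function() {
  data.frame(elety = c("N", "CA", "C", "O"), resid = "ALA", chain = "A",
             resno = 1L, insert = "", alt = "", occupancy = 1,
             x = c(0, 1.46, 2.0, 3.2), y = c(0, 0, 1.4, 1.5),
             z = c(0, 0, 0, 0.1), elesy = c("N", "C", "C", "O"),
             stringsAsFactors = FALSE)
}

# random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# memoized closed-loop runs shared between the module and acceptance tests
.closed_loop_cache <- new.env(parent = emptyenv())
closed_loop_cached <- function(seed, outlier_fraction = 0) {
  key <- paste0("s", seed, "_o", outlier_fraction)
  if (is.null(.closed_loop_cache[[key]]))
    .closed_loop_cache[[key]] <- closed_loop_recovery(
      seed = seed, outlier_fraction = outlier_fraction)
  .closed_loop_cache[[key]]
}
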