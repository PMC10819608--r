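# shared fixtures built in code

rest_g <- c(1.923, 2.253, 2.443)

h1_nucleus <- function() {
  nucleus("1H", axial_hyperfine(-0.09, 5.60, 0, 22), label = "H1")
}

n1_nucleus <- function(n_equiv = 1) {
  nucleus("14N",
          interaction_tensor(c(-4.90, -4.80, -5.10), c(90, 0, 0),
                             "hyperfine"),
          interaction_tensor(c(0.90, -0.60, -0.30), c(90, 0, 0),
                             "quadrupole"),
          label = "N1", n_equivalent = n_equiv)
}

n3_nucleus <- function(alpha = 65) {
  nucleus("14N",
          interaction_tensor(c(-3.57, -3.20, -2.54), c(alpha, 0, 0),
                             "hyperfine"),
          interaction_tensor(c(0.30, 0.80, -1.10), c(alpha, 0, 0),
                             "quadrupole"),
          label = "N3")
}

# nearly isotropic g: the whole powder falls inside the excitation
# window, so full-sphere ridges are sampled
iso_g <- c(2.000, 2.002, 2.004)
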