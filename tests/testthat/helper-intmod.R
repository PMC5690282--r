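# shared fixtures built in code

# a minimal Calpha-only structure from a coordinate matrix
ca_struct <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                      id = "toy") {
  new_structure(data.frame(
    chain = chain, resno = resno, inscode = "", resname = "ALA",
    atom = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]), id = id)
}

# restraint table from explicit sites
make_restraints <- function(chain_a, res_a, chain_b, res_b,
                            target = 11.4, upper = 30, weight = 1,
                            chemistry = "BS3") {
  df <- data.frame(chain_a = chain_a, res_a = res_a, chain_b = chain_b,
                   res_b = res_b, target = target, lower = 0, upper = upper,
                   weight = weight, chemistry = chemistry,
                   stringsAsFactors = FALSE)
  class(df) <- c("restraints", "data.frame")
  df
}

bs3_fixture <- function() {
  system.file("extdata", "bs3_crosslinks.txt", package = "intmod")
}

hdx_fixture <- function() {
  system.file("extdata", "hdx_deltaD.txt", package = "intmod")
}

# CSMs for one protein pair out of the bundled three-block table
csms_for_pair <- function(a, b) {
  cs <- parse_csm_table(bs3_fixture())
  keep <- (cs$protein_a == a & cs$protein_b == b) |
          (cs$protein_a == b & cs$protein_b == a)
  cs[keep, , drop = FALSE]
}

# analytic sphere scattering curve (radius R, forward intensity I0)
sphere_curve <- function(R = 30, I0 = 1,
                         s = seq(0.003, 0.497, length.out = 300)) {
  ff <- (3 * (sin(s * R) - s * R * cos(s * R)) / (s * R)^3)^2
  saxs_curve(s, I0 * ff)
}
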