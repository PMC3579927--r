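# Small in-code fixtures shared across tests.

random_descriptors <- function() {
  descriptor_vector(hba = sample(0:10, 1), hbd = sample(0:10, 1),
                    logS = runif(1, -6, 0), slogp = runif(1, -1, 5),
                    mw = runif(1, 150, 550), rotbonds = sample(0:10, 1),
                    tpsa = runif(1, 20, 140))
}

random_tagged_molecule <- function(id, n_atoms = 10) {
  tags <- replicate(n_atoms, paste(
    FEATURE_TYPES[runif(6) < c(0.3, 0.3, 0.1, 0.1, 0.3, 0.4)], collapse = "|"))
  if (!any(nzchar(tags))) tags[1] <- "donor"
  molecule_record(id,
                  atoms = atom_table(rep("C", n_atoms), rnorm(n_atoms, 0, 3),
                                     rnorm(n_atoms, 0, 3), rnorm(n_atoms, 0, 3),
                                     tags = tags),
                  descriptors = random_descriptors())
}

# Vertices of a regular tetrahedron with edge length 2*sqrt(2).
tetrahedron_coords <- function() {
  matrix(c(1, 1, 1,
           1, -1, -1,
           -1, 1, -1,
           -1, -1, 1), ncol = 3, byrow = TRUE)
}
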