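# Shared vocabularies and feature dimensions (collated first).

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")
.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)
# element vocabulary for featurization / fingerprint hashing
.ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")

.N_ELEM_FEAT <- length(.ELEMENT_VOCAB) + 1L  # + "other"
.N_DEG_FEAT <- 6L                            # degree 0..5+
.N_H_FEAT <- 5L                              # H count 0..4+
.D_ATOM <- .N_ELEM_FEAT + .N_DEG_FEAT + .N_H_FEAT + 2L  # + charge + aromatic
.D_BOND <- 6L                                # order one-hot(4) + conj + ring

.UNIT_TO_UM <- c(M = 1e6, mM = 1e3, uM = 1, nM = 1e-3, pM = 1e-6)
.METRICS <- c("KI", "IC50", "EC50", "KD")
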