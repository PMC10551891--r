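# Package-wide constants (this file collates first).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Accepted sequence alphabet: the 20 standard residues plus X (unknown).
VALID_AA <- paste0(paste(AA20, collapse = ""), "X")
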