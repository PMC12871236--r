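# Shared constants (this file sorts first so every module can use them at
# source time).

BRACKET_OPEN  <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

RNA_BASES <- c("A", "C", "G", "U")

# complements under the canonical pairs A-U, G-C, G-U
CANONICAL_COMPLEMENTS <- list(
  A = "U",
  C = "G",
  G = c("C", "U"),
  U = c("A", "G")
)

ENC_VOCAB <- c(".", BRACKET_OPEN, BRACKET_CLOSE)        # 9 structure tokens
DEC_VOCAB <- c(RNA_BASES, "START", "PAD")               # 6 sequence tokens
START_TOKEN <- 5L
PAD_TOKEN <- 6L
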