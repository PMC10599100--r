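# Internal helpers shared across modules.

# The twenty standard residues, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  X =  0.0
)

# Split a sequence into a character vector of residues.
seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

# Per-residue hydropathy; X and unknowns score 0.
kd_values <- function(sequence) {
  v <- KD_SCALE[seq_chars(toupper(sequence))]
  v[is.na(v)] <- 0
  unname(v)
}

# Rolling mean of window `w` over x; value i corresponds to the window
# starting at position i (1-based), length(x) - w + 1 values.
roll_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

# Uppercase a protein sequence and map non-standard residues to X.
sanitize_protein <- function(sequence, context = NULL) {
  s <- toupper(sequence)
  ch <- seq_chars(s)
  bad <- !(ch %in% c(AA20, "X"))
  if (any(bad)) {
    warn(sprintf("%s: %d ambiguous residue(s) (%s) mapped to X",
                 context %||% "sequence", sum(bad),
                 paste(unique(ch[bad]), collapse = ",")))
    ch[bad] <- "X"
    s <- paste(ch, collapse = "")
  }
  s
}

# Relevant architecture classes, in census order.
RELEVANT_CLASSES <- c("WXLIP_FULL", "WXL_SMALL", "WXL_LARGE",
                      "PGBD_ONLY", "HBD_ONLY")

stopifnot_scalar_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("file not found: %s", paste(path, collapse = ", ")))
  }
  invisible(path)
}
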