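# Independent reference implementations used as oracles. These are
# deliberately naive (substring scans, literal criterion transcription)
# and share no code with the package internals they check.

# promoter classification by brute-force window recounting
brute_classify <- function(seq, window = 500L, step = 20L) {
  s <- toupper(seq)
  L <- nchar(s)
  offs <- if (L < window) integer(0) else seq(0L, L - window, by = step)
  ratio <- gc <- numeric(length(offs))
  for (k in seq_along(offs)) {
    ch <- strsplit(substr(s, offs[k] + 1, offs[k] + window), "")[[1]]
    ch_nn <- ch[ch != "N"]
    nc <- sum(ch_nn == "C"); ng <- sum(ch_nn == "G")
    ncpg <- 0L
    for (i in seq_len(length(ch) - 1))
      if (ch[i] == "C" && ch[i + 1] == "G") ncpg <- ncpg + 1L
    len <- length(ch_nn)
    ratio[k] <- if (nc > 0 && ng > 0) ncpg * len / (nc * ng) else 0
    gc[k] <- if (len > 0) 100 * (nc + ng) / len else 0
  }
  if (any(ratio > 0.65 & gc > 55)) "HCP"
  else if (!any(ratio > 0.45)) "LCP"
  else "ICP"
}

# literal transcription of the seven cryptic-initiation criteria for a
# single-isoform gene (criterion iii reduces to criterion i there)
brute_cryptic_accept <- function(up, fc, fpkm_up) {
  n <- length(up)
  idx <- which(up)
  k <- length(idx)
  if (k == 0) return(FALSE)
  if (!(k / n < 1)) return(FALSE)                          # (i) + (iii)
  if (up[1]) return(FALSE)                                 # (ii)
  if (k < 5) {
    if (!all(diff(idx) == 1)) return(FALSE)                # (iv)
  } else {
    if (sum(!up[min(idx):max(idx)]) > 1) return(FALSE)     # (v)
  }
  if (!(mean(fc[idx]) > 3 * mean(fc[-idx]))) return(FALSE) # (vi)
  if (!(mean(fpkm_up[idx]) > mean(fpkm_up[-idx]))) return(FALSE) # (vii)
  TRUE
}
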