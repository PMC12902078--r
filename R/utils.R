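## Shared helpers: intervals, reverse complement, seeded sub-streams, Phred.

#' Union of 1-based inclusive intervals
#' @param intervals list of length-2 integer vectors `c(start, end)`
#' @return matrix with columns start, end; disjoint, sorted
#' @keywords internal
interval_union <- function(intervals) {
  if (length(intervals) == 0) return(matrix(integer(0), ncol = 2,
                                            dimnames = list(NULL, c("start", "end"))))
  m <- do.call(rbind, lapply(intervals, function(x) as.integer(x[1:2])))
  if (any(m[, 1] > m[, 2])) stop("interval start exceeds end")
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2] + 1L) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, ])
    }
  }
  colnames(out) <- c("start", "end")
  out
}

in_intervals <- function(pos, intervals) {
  hit <- rep(FALSE, length(pos))
  for (iv in intervals) hit <- hit | (pos >= iv[1] & pos <= iv[2])
  hit
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a reproducible sub-stream seed from a master seed and labels
#'
#' Hashes the labels with a small polynomial rolling hash so that adding a
#' sample or stage never perturbs the random stream of another.
#' @keywords internal
derive_seed <- function(master, ...) {
  labs <- paste(c(...), collapse = "\r")
  h <- as.double(master %% 2147483647L)
  for (cp in utf8ToInt(labs)) h <- (h * 131 + cp) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

phred_to_char <- function(q) {
  intToUtf8(pmin(pmax(q, 0), 93) + 33L, multiple = FALSE)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

## split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_acgt <- function(chars) chars %in% BASES
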