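# Independent oracles used across the suite. None of these call the
# package's own routines for the quantity they check.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
ASTV <- c("A", "S", "T", "V")

rand_seq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- N-glycosylation sequon: brute-force window enumeration -----------------
oracle_nglyc <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < 3L) return(integer(0))
  which(chars[1:(L - 2)] == "N" &
        !(chars[2:(L - 1)] %in% c("P", "X")) &
        chars[3:L] %in% c("S", "T"))
}

# --- O-glycosylation consensus: backtracking with lazy semantics ------------
# Enumerates (p1, spacer, p2) in lexicographic ascending order at each start,
# leftmost, non-overlapping; resumes after the end of each accepted match.
oracle_oglyc_at <- function(chars, s) {
  L <- length(chars)
  if (!(chars[s] %in% ASTV)) return(NULL)
  for (p1 in 1:4) {
    j <- s + p1
    if (j > L || chars[j] != "P") break
    for (sp in 0:10) {
      a2 <- j + sp + 1L
      if (a2 > L) break
      if (sp > 0 && !(chars[j + sp] %in% AA20)) break
      if (!(chars[a2] %in% ASTV)) next
      for (p2 in 1:4) {
        k <- a2 + p2
        if (k > L || chars[k] != "P") break
        return(list(start = s, end = k, site = a2 + 1L))
      }
    }
  }
  NULL
}

oracle_oglyc <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  res <- list()
  s <- 1L
  while (s <= L - 3L) {
    m <- oracle_oglyc_at(chars, s)
    if (is.null(m)) s <- s + 1L
    else {
      res[[length(res) + 1L]] <- m
      s <- m$end + 1L
    }
  }
  if (!length(res))
    return(data.frame(start = integer(0), end = integer(0),
                      site = integer(0)))
  data.frame(start = vapply(res, `[[`, 0L, "start"),
             end = vapply(res, `[[`, 0L, "end"),
             site = vapply(res, `[[`, 0L, "site"))
}

# --- Global identity: Needleman-Wunsch DP with traceback --------------------
# Score = matches - gaps (match 1, mismatch 0, linear gap -1); identity =
# matches / alignment columns on the recovered optimal path. 'X' never
# counts as a match.
oracle_nw_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[1, ] <- -(0:m); S[, 1] <- -(0:n)
  mt <- function(i, j) as.integer(A[i] == B[j] && A[i] != "X")
  for (i in 1:n) for (j in 1:m)
    S[i + 1, j + 1] <- max(S[i, j] + mt(i, j),
                           S[i, j + 1] - 1, S[i + 1, j] - 1)
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + mt(i, j)) {
      matches <- matches + mt(i, j); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1L
  }
  matches / cols
}

# Brute-force greedy clustering applying the same order as the package but
# the oracle's own identity routine.
oracle_greedy_clusters <- function(ids, seqs, cutoff) {
  ord <- order(-nchar(seqs), ids)
  reps <- integer(0)
  for (i in ord) {
    hit <- FALSE
    for (r in reps)
      if (oracle_nw_identity(seqs[i], seqs[r]) >= cutoff) { hit <- TRUE; break }
    if (!hit) reps <- c(reps, i)
  }
  sort(ids[reps])
}

# --- One-tailed t probability by numerical integration ----------------------
# Integrates the Student-t density written out from its gamma closed form;
# independent of stats::pt / stats::dt.
oracle_one_tailed_p <- function(r, n) {
  df <- n - 2
  t0 <- abs(r) * sqrt(df / (1 - r^2))
  konst <- gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2))
  f <- function(x) konst * (1 + x^2 / df)^(-(df + 1) / 2)
  stats::integrate(f, t0, Inf, rel.tol = 1e-10)$value
}

# --- Printed correlation table (r over p), transcribed values ---------------
# p = NA encodes a "<0.0001" entry (an upper bound, not an equality target).
# All columns reproduce from r at n = 5 except K-ace, which requires n = 8.
table1_data <- function() {
  rows <- list(
    Arabidopsis  = list(r = c(0.996, 0.983, 0.975, 0.976, 0.692, 0.975, -0.893),
                        p = c(0.0002, 0.0013, 0.0024, 0.0022, 0.0977, NA, 0.0207)),
    Soybean      = list(r = c(0.993, 0.970, 0.989, 0.981, 0.675, 0.959, -0.847),
                        p = c(0.0004, 0.0031, 0.0007, 0.0016, 0.1056, NA, 0.0351)),
    Poplar       = list(r = c(0.996, 0.976, 0.963, 0.996, 0.892, 0.976, -0.923),
                        p = c(0.0002, 0.0022, 0.0042, 0.0002, 0.0209, NA, 0.0127)),
    Grape        = list(r = c(0.995, 0.972, 0.968, 0.996, 0.789, 0.972, -0.914),
                        p = c(0.0002, 0.0028, 0.0034, 0.0002, 0.0563, NA, 0.0149)),
    Tomato       = list(r = c(0.993, 0.975, 0.969, 0.991, 0.875, 0.950, -0.854),
                        p = c(0.0004, 0.0024, 0.0033, 0.0005, 0.0260, 0.0002, 0.0327)),
    Rice         = list(r = c(0.979, 0.998, 0.951, 0.922, -0.450, 0.761, -0.142),
                        p = c(0.0018, NA, 0.0065, 0.0129, 0.2235, 0.0140, 0.4099)),
    Brachypodium = list(r = c(0.992, 0.995, 0.992, 0.952, -0.040, 0.951, -0.782),
                        p = c(0.0004, 0.0002, 0.0004, 0.0063, 0.4745, 0.0002, 0.0591)),
    Sorghum      = list(r = c(0.993, 0.994, 0.996, 0.957, -0.301, 0.943, -0.798),
                        p = c(0.0004, 0.0003, 0.0002, 0.0053, 0.3113, 0.0002, 0.0528)))
  ptms <- c("pSer", "pThr", "pTyr", "O-gly", "N-gly", "K-ace", "R-met")
  out <- do.call(rbind, lapply(names(rows), function(sp)
    data.frame(species = sp, ptm = ptms, r = rows[[sp]]$r, p = rows[[sp]]$p,
               n = ifelse(ptms == "K-ace", 8L, 5L),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

# Check one printed (r, p) cell: the p recomputed from the printed r must
# round to within one unit in the 4th decimal of the printed p, or the
# printed p must be reachable from some r inside the half-ulp interval of
# the printed (3-decimal) r.
table1_cell_ok <- function(r, p_printed, n) {
  if (is.na(p_printed))                       # "<0.0001": an upper bound
    return(one_tailed_p(r, n) < 1e-4)
  if (abs(round(one_tailed_p(r, n), 4) - p_printed) <= 1e-4 + 1e-12)
    return(TRUE)
  lo <- one_tailed_p(abs(r) + 5e-4, n)        # p monotone decreasing in |r|
  hi <- one_tailed_p(abs(r) - 5e-4, n)
  p_printed >= round(lo, 4) - 1e-4 - 1e-12 &&
    p_printed <= round(hi, 4) + 1e-4 + 1e-12
}
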