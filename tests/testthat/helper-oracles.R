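# Independent brute-force oracles. These share no code with the package:
# plain loops, list-of-matrices dynamic programming, and exhaustive
# enumeration, used to verify the package's vectorized / compiled paths.

naive_smooth <- function(x, window) {
  n <- length(x)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    out[i] <- mean(x[lo:hi])
  }
  out
}

naive_runs <- function(x, cutoff) {
  segs <- list()
  i <- 1
  n <- length(x)
  while (i <= n) {
    if (x[i] > cutoff) {
      j <- i
      while (j < n && x[j + 1] > cutoff) j <- j + 1
      segs[[length(segs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  segs
}

# pairwise merge loop run to fixpoint
naive_merge <- function(segs, max_gap) {
  repeat {
    changed <- FALSE
    if (length(segs) >= 2) {
      for (k in seq_len(length(segs) - 1)) {
        gap <- segs[[k + 1]][1] - segs[[k]][2] - 1
        if (gap <= max_gap) {
          segs[[k]] <- c(segs[[k]][1], segs[[k + 1]][2])
          segs[[k + 1]] <- NULL
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  segs
}

naive_segment <- function(track, smooth_window = 7, cutoff = 0.45,
                          merge_gap = 7, min_length = 30) {
  sm <- naive_smooth(track, smooth_window)
  segs <- naive_merge(naive_runs(sm, cutoff), merge_gap)
  segs <- Filter(function(s) (s[2] - s[1] + 1) >= min_length, segs)
  if (length(segs) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(
    start = vapply(segs, `[[`, numeric(1), 1),
    end = vapply(segs, `[[`, numeric(1), 2)
  )
}

naive_charges <- function(seq) {
  res <- strsplit(toupper(seq), "")[[1]]
  out <- integer(length(res))
  for (i in seq_along(res)) {
    out[i] <- if (res[i] %in% c("K", "R")) 1L else if (res[i] %in% c("D", "E")) -1L else 0L
  }
  out
}

naive_ncpr <- function(seq, window = 5) {
  naive_smooth(naive_charges(seq), window)
}

naive_tracts <- function(prof) {
  tr <- list()
  i <- 1
  n <- length(prof)
  while (i <= n) {
    if (prof[i] != 0) {
      s <- sign(prof[i])
      j <- i
      while (j < n && sign(prof[j + 1]) == s) j <- j + 1
      area <- 0
      for (k in i:j) area <- area + prof[k]
      tr[[length(tr) + 1]] <- list(start = i, end = j, sign = s, area = abs(area))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  tr
}

naive_filtered_area <- function(prof, min_area = 1) {
  # same boundary convention as the package: exact-threshold tracts (within
  # 1e-9) do not pass the strict filter
  tot <- 0
  for (t in naive_tracts(prof)) if (t$area > min_area + 1e-9) tot <- tot + t$area
  tot
}

naive_sigma <- function(fp, fm) {
  if (fp + fm == 0) 0 else (fp - fm)^2 / (fp + fm)
}

naive_delta <- function(charges, blob) {
  n <- length(charges)
  sg <- naive_sigma(sum(charges == 1) / n, sum(charges == -1) / n)
  tot <- 0
  for (i in 1:(n - blob + 1)) {
    w <- charges[i:(i + blob - 1)]
    tot <- tot + (naive_sigma(sum(w == 1) / blob, sum(w == -1) / blob) - sg)^2
  }
  tot / (n - blob + 1)
}

# all distinct arrangements of a charge multiset, as integer vectors
multiset_perms <- function(p, m, z) {
  out <- list()
  recur <- function(prefix, p, m, z) {
    if (p + m + z == 0) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    if (p > 0) recur(c(prefix, 1L), p - 1L, m, z)
    if (m > 0) recur(c(prefix, -1L), p, m - 1L, z)
    if (z > 0) recur(c(prefix, 0L), p, m, z - 1L)
  }
  recur(integer(0), p, m, z)
  out
}

exhaustive_dmax <- function(p, m, z, blob) {
  best <- -Inf
  for (ch in multiset_perms(p, m, z)) {
    d <- naive_delta(ch, blob)
    if (d > best) best <- d
  }
  best
}

# Independent exact maximization of delta over arrangements: dynamic program
# over the tuple of the last (blob - 1) placed residues, kept as a list of
# (p_used + 1) x (m_used + 1) value matrices, one per window-suffix state.
oracle_dmax <- function(p, m, z, blob) {
  n <- p + m + z
  if (p + m == 0) {
    return(0)
  }
  S <- 3^(blob - 1)
  cntP <- integer(S)
  cntM <- integer(S)
  for (s in 0:(S - 1)) {
    t <- s
    for (k in seq_len(blob - 1)) {
      d <- t %% 3
      t <- t %/% 3
      if (d == 1) cntP[s + 1] <- cntP[s + 1] + 1
      if (d == 2) cntM[s + 1] <- cntM[s + 1] + 1
    }
  }
  sg <- naive_sigma(p / n, m / n)
  P1 <- p + 1
  M1 <- m + 1
  a_idx <- matrix(0:(P1 - 1), P1, M1)
  b_idx <- matrix(0:(M1 - 1), P1, M1, byrow = TRUE)
  neg_mat <- matrix(-Inf, P1, M1)
  shiftA <- function(M) rbind(rep(-Inf, M1), M[-P1, , drop = FALSE])
  shiftB <- function(M) cbind(rep(-Inf, P1), M[, -M1, drop = FALSE])
  cur <- vector("list", S)
  start <- neg_mat
  start[1, 1] <- 0
  cur[[1]] <- start
  for (i in 0:(n - 1)) {
    nxt <- vector("list", S)
    scoring <- (i + 1) >= blob
    accum <- function(t, M) {
      if (is.null(nxt[[t]])) nxt[[t]] <<- M else nxt[[t]] <<- pmax(nxt[[t]], M)
    }
    for (s in 0:(S - 1)) {
      slice <- cur[[s + 1]]
      if (is.null(slice)) next
      ns0 <- (s * 3) %% S
      # place a neutral residue (if any remain)
      w <- slice
      if (scoring) w <- w + (naive_sigma(cntP[s + 1] / blob, cntM[s + 1] / blob) - sg)^2
      w[(i - a_idx - b_idx) >= z] <- -Inf
      accum(ns0 + 1, w)
      if (p > 0) {
        w <- slice
        if (scoring) w <- w + (naive_sigma((cntP[s + 1] + 1) / blob, cntM[s + 1] / blob) - sg)^2
        accum(ns0 + 2, shiftA(w))
      }
      if (m > 0) {
        w <- slice
        if (scoring) w <- w + (naive_sigma(cntP[s + 1] / blob, (cntM[s + 1] + 1) / blob) - sg)^2
        accum(ns0 + 3, shiftB(w))
      }
    }
    cur <- nxt
  }
  best <- -Inf
  for (s in seq_len(S)) {
    if (!is.null(cur[[s]]) && cur[[s]][P1, M1] > best) best <- cur[[s]][P1, M1]
  }
  best / (n - blob + 1)
}

oracle_kappa <- function(seq, blobs = c(5, 6)) {
  ch <- naive_charges(seq)
  terms <- numeric(0)
  for (g in blobs) {
    if (length(ch) < g) next
    dm <- oracle_dmax(sum(ch == 1), sum(ch == -1), sum(ch == 0), g)
    if (dm > 0) terms <- c(terms, naive_delta(ch, g) / dm)
  }
  if (length(terms) == 0) {
    return(NA_real_)
  }
  mean(terms)
}

# end-to-end naive scoring of one IDR sequence (exhaustive or DP kappa)
naive_score_idr <- function(seq, exhaustive = FALSE) {
  prof <- naive_ncpr(seq, 5)
  fas <- naive_filtered_area(prof, 1)
  ch <- naive_charges(seq)
  k <- if (exhaustive) {
    terms <- numeric(0)
    for (g in c(5, 6)) {
      if (length(ch) < g) next
      dm <- exhaustive_dmax(sum(ch == 1), sum(ch == -1), sum(ch == 0), g)
      if (dm > 0) terms <- c(terms, naive_delta(ch, g) / dm)
    }
    if (length(terms) == 0) NA_real_ else mean(terms)
  } else {
    oracle_kappa(seq)
  }
  mult <- (0.6 + ifelse(is.na(k), 0, k))^2
  list(filtered_area_sum = fas, kappa = k, multiplier = mult, score = fas * mult)
}

random_aa_seq <- function(n, charged_frac = 0.25) {
  neutral <- c("G", "S", "A", "P", "Q", "N", "T", "H", "Y", "F", "L", "V")
  charged <- c("D", "E", "K", "R")
  paste(sample(
    c(charged, neutral),
    size = n, replace = TRUE,
    prob = c(rep(charged_frac / 4, 4), rep((1 - charged_frac) / 12, 12))
  ), collapse = "")
}
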