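# Synthetic sequences, disorder tracks and mini-proteomes with controlled
# charge architecture. Deterministic for a fixed seed; noise off by default
# so fixture assertions can be exact.

#' Generate a protein sequence with a designed charge architecture
#'
#' Archetypes: `diblock` (neutral flank, D block, K block, neutral flank),
#' `alternating` (strict DK alternation between flanks), `uncharged` (all
#' neutral), `scrambled` (seeded uniform permutation of the diblock's
#' letters), and `npm1_multiblock` (alternating acidic and basic blocks
#' separated by neutral spacers, mimicking a multi-tract nucleolar IDR).
#' The neutral filler is glycine.
#'
#' @param archetype One of the architecture names above.
#' @param n_neg,n_pos Number of D and K residues.
#' @param flank_len Neutral residues on each side.
#' @param block_len Block size for `npm1_multiblock`.
#' @param spacer_len Neutral spacer between blocks for `npm1_multiblock`.
#' @param seed Integer seed; required for `scrambled`.
#' @return A single sequence string.
#' @examples
#' make_sequence("diblock") # "G...GD...DK...KG...G", 50 residues
#' make_sequence("alternating", flank_len = 0) # "DKDK...", 30 residues
#' @export
make_sequence <- function(archetype = c(
                            "diblock", "alternating", "uncharged",
                            "scrambled", "npm1_multiblock"
                          ),
                          n_neg = 15L, n_pos = 15L, flank_len = 10L,
                          block_len = 8L, spacer_len = 4L, seed = NULL) {
  archetype <- match.arg(archetype)
  n_neg <- as.integer(n_neg)
  n_pos <- as.integer(n_pos)
  flank_len <- as.integer(flank_len)
  if (n_neg < 0L || n_pos < 0L || flank_len < 0L) {
    stop("residue counts must be non-negative", call. = FALSE)
  }
  flank <- strrep("G", flank_len)
  core <- switch(archetype,
    diblock = paste0(strrep("D", n_neg), strrep("K", n_pos)),
    uncharged = strrep("G", n_neg + n_pos),
    alternating = {
      letters <- character(0)
      d <- n_neg
      k <- n_pos
      take_d <- TRUE
      while (d > 0L || k > 0L) {
        if ((take_d && d > 0L) || k == 0L) {
          letters <- c(letters, "D")
          d <- d - 1L
        } else {
          letters <- c(letters, "K")
          k <- k - 1L
        }
        take_d <- !take_d
      }
      paste(letters, collapse = "")
    },
    scrambled = {
      if (is.null(seed)) stop("`scrambled` requires a seed", call. = FALSE)
      full <- paste0(flank, strrep("D", n_neg), strrep("K", n_pos), flank)
      letters <- strsplit(full, "", fixed = TRUE)[[1]]
      perm <- withr::with_seed(seed, sample.int(length(letters)))
      return(assert_nonempty(paste(letters[perm], collapse = "")))
    },
    npm1_multiblock = {
      spacer <- strrep("G", as.integer(spacer_len))
      blocks <- character(0)
      d <- n_neg
      k <- n_pos
      neg_turn <- TRUE
      while (d > 0L || k > 0L) {
        if (neg_turn && d > 0L) {
          take <- min(block_len, d)
          blocks <- c(blocks, strrep("D", take))
          d <- d - take
        } else if (!neg_turn && k > 0L) {
          take <- min(block_len, k)
          blocks <- c(blocks, strrep("K", take))
          k <- k - take
        }
        neg_turn <- !neg_turn
      }
      paste(blocks, collapse = spacer)
    }
  )
  assert_nonempty(paste0(flank, core, flank))
}

assert_nonempty <- function(seq) {
  if (nchar(seq) == 0L) stop("generated sequence has zero length", call. = FALSE)
  seq
}

#' Generate a disorder track with designed IDR spans
#'
#' Scores are `in_value` on the given spans and `out_value` elsewhere,
#' optionally perturbed by seeded Gaussian noise, then clipped to \[0, 1\].
#'
#' @param length Track length in residues.
#' @param idr_spans List of `c(start, end)` pairs (1-based inclusive), or a
#'   two-column matrix; spans must be in range and non-overlapping.
#' @param in_value,out_value Disorder propensity inside/outside the spans.
#' @param noise_sd Standard deviation of the optional Gaussian noise
#'   (default 0: exact values).
#' @param seed Integer seed for the noise.
#' @return Numeric vector of length `length`.
#' @examples
#' make_disorder_track(50, list(c(1, 50)))
#' @export
make_disorder_track <- function(length, idr_spans, in_value = 0.9,
                                out_value = 0.1, noise_sd = 0, seed = NULL) {
  length <- as.integer(length)
  if (is.matrix(idr_spans)) {
    idr_spans <- lapply(seq_len(nrow(idr_spans)), function(i) idr_spans[i, ])
  }
  x <- rep(out_value, length)
  covered <- logical(length)
  for (span in idr_spans) {
    s <- as.integer(span[1])
    e <- as.integer(span[2])
    if (s < 1L || e > length || s > e) {
      stop(sprintf("span [%d, %d] out of range for length %d", s, e, length),
        call. = FALSE
      )
    }
    if (any(covered[s:e])) stop("overlapping IDR spans", call. = FALSE)
    covered[s:e] <- TRUE
    x[s:e] <- in_value
  }
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) {
      rnorm(length, 0, noise_sd)
    } else {
      withr::with_seed(seed, rnorm(length, 0, noise_sd))
    }
    x <- x + noise
  }
  pmin(1, pmax(0, x))
}

write_fasta_plain <- function(accessions, sequences, path, width = 60L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(accessions)) {
    writeLines(paste0(">", accessions[i]), con, sep = "\n")
    s <- sequences[i]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con, sep = "\n")
  }
  invisible(path)
}

write_track_iupred <- function(sequence, track, path) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# POS\tRES\tIUPRED2", con, sep = "\n")
  writeLines(sprintf("%d\t%s\t%.4f", seq_along(res), res, track), con, sep = "\n")
  invisible(path)
}

#' Generate a self-consistent synthetic mini-proteome on disk
#'
#' Writes a FASTA file, one IUPRED-long-format track per protein (fully
#' disordered at 0.9) and a manifest TSV recording each protein's
#' archetype. The archetype mix implies a known qualitative score
#' ordering at default parameters: every diblock protein outscores every
#' scrambled one or ties it, and alternating and uncharged proteins score
#' exactly 0.
#'
#' @param outdir Output directory; created if needed.
#' @param n_proteins Number of proteins; must be at least the number of
#'   archetypes in `mix`.
#' @param seed Integer seed controlling scrambled permutations.
#' @param mix Named fractions over archetypes, summing to 1.
#' @return Invisibly, a list with `fasta`, `disorder_dir` and `manifest`
#'   paths.
#' @export
make_synthetic_proteome <- function(outdir, n_proteins = 100L, seed = 1L,
                                    mix = c(
                                      diblock = 0.25, alternating = 0.25,
                                      uncharged = 0.25, scrambled = 0.25
                                    )) {
  n_proteins <- as.integer(n_proteins)
  if (abs(sum(mix) - 1) > 1e-8) stop("`mix` fractions must sum to 1", call. = FALSE)
  if (n_proteins < length(mix)) {
    stop(sprintf(
      "n_proteins = %d is too small for %d archetypes", n_proteins, length(mix)
    ), call. = FALSE)
  }
  counts <- floor(mix * n_proteins)
  rem <- n_proteins - sum(counts)
  if (rem > 0L) {
    bump <- rep(seq_along(mix), length.out = rem)
    counts[bump] <- counts[bump] + 1L
  }
  archetypes <- rep(names(mix), counts)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  track_dir <- file.path(outdir, "tracks")
  if (!dir.exists(track_dir)) dir.create(track_dir)
  accs <- sprintf("SYN%04d", seq_len(n_proteins))
  seqs <- character(n_proteins)
  for (i in seq_len(n_proteins)) {
    seqs[i] <- make_sequence(
      archetypes[i],
      seed = (as.integer(seed) * 131L + i) %% .Machine$integer.max
    )
  }
  fasta <- file.path(outdir, "proteome.fasta")
  write_fasta_plain(accs, seqs, fasta)
  for (i in seq_len(n_proteins)) {
    track <- make_disorder_track(nchar(seqs[i]), list(c(1L, nchar(seqs[i]))))
    write_track_iupred(seqs[i], track, file.path(track_dir, paste0(accs[i], ".iupred")))
  }
  manifest <- file.path(outdir, "manifest.tsv")
  con <- file(manifest, open = "wb")
  writeLines(
    c(
      "accession\tarchetype\tlength",
      sprintf("%s\t%s\t%d", accs, archetypes, nchar(seqs))
    ),
    con,
    sep = "\n"
  )
  close(con)
  invisible(list(fasta = fasta, disorder_dir = track_dir, manifest = manifest))
}
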