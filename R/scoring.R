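# Tissue score tracks at fixed 25 bp resolution.
#
# In memory a track set is a list: tissues -> chromosomes -> numeric vector
# of bin values, where bin b covers positions [(b-1)*25 + 1, b*25] (1-based
# inclusive; hg19 convention). On disk each tissue is a bedGraph file with
# fixed 25 bp steps (0-based half-open intervals).

#' Bin size of the score tracks (bp)
#' @export
track_bin_size <- 25L

#' Map genomic positions to track bins
#'
#' Bin `b` covers positions `[(b-1)*25 + 1, b*25]`, so position 1 through 25
#' map to bin 1 and position 26 to bin 2 (0-based bin index `floor((pos-1)/25)`).
#'
#' @param pos 1-based genomic positions.
#' @return 1-based bin indices.
#' @export
position_to_bin <- function(pos) {
  stopifnot(all(pos >= 1))
  (as.integer(pos) - 1L) %/% track_bin_size + 1L
}

#' Build an in-memory track set
#'
#' @param tracks List: tissue name -> list(chromosome name -> numeric
#'   vector of 25 bp bin values).
#' @return The validated list with class `tissue_tracks`.
#' @export
tissue_tracks <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1L, !is.null(names(tracks)))
  structure(tracks, class = "tissue_tracks")
}

#' Read fixed-step bedGraph tracks
#'
#' Reads one bedGraph file per tissue (0-based half-open intervals on a
#' fixed 25 bp grid) into a [tissue_tracks()] object. Uncovered bins are
#' zero. Parsing is delegated to `rtracklayer`.
#'
#' @param files Named character vector: tissue name -> bedGraph path.
#' @return A `tissue_tracks` object.
#' @export
read_tissue_tracks <- function(files) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading bedGraph tracks requires the 'rtracklayer' package")
  }
  stopifnot(!is.null(names(files)))
  tracks <- lapply(files, function(f) {
    gr <- rtracklayer::import(f, format = "bedGraph")
    starts <- GenomicRanges::start(gr) # 1-based after import
    ends <- GenomicRanges::end(gr)
    if (any((starts - 1L) %% track_bin_size != 0L) ||
        any((ends - starts + 1L) %% track_bin_size != 0L)) {
      stop("track ", f, " is not on a fixed ", track_bin_size, " bp grid")
    }
    chroms <- as.character(GenomicRanges::seqnames(gr))
    out <- list()
    for (ch in unique(chroms)) {
      sel <- chroms == ch
      last_bin <- max(position_to_bin(ends[sel]))
      v <- numeric(last_bin)
      for (i in which(sel)) {
        b0 <- position_to_bin(starts[i])
        b1 <- position_to_bin(ends[i])
        v[b0:b1] <- gr$score[i]
      }
      out[[ch]] <- v
    }
    out
  })
  tissue_tracks(tracks)
}

#' Score genomic positions with a fitted disease model
#'
#' Looks up each position's 25 bp bin in every tissue track, assembles the
#' per-position tissue score vector and applies the fitted model:
#' `score = inverse-logit(a0 + a * xbar + beta' x)`. Positions outside the
#' track bounds (or on chromosomes without a track) receive `NA` with a
#' warning.
#'
#' @param fit A `model_fit` (tissue order must match the track names).
#' @param tracks A [tissue_tracks()] object.
#' @param positions Data frame with `chrom` and `pos` columns.
#' @return Data frame `chrom`, `pos`, `score`.
#' @export
score_positions <- function(fit, tracks, positions) {
  stopifnot(inherits(fit, "model_fit"), inherits(tracks, "tissue_tracks"))
  tissues <- names(tracks)
  if (!identical(sort(tissues), sort(names(fit$tissue_coefs)))) {
    stop("track tissues do not match the fitted tissue coefficients")
  }
  tracks <- tracks[names(fit$tissue_coefs)]
  n <- nrow(positions)
  bins <- position_to_bin(positions$pos)
  X <- matrix(NA_real_, nrow = n, ncol = length(tissues),
              dimnames = list(NULL, names(fit$tissue_coefs)))
  for (t in seq_along(tracks)) {
    for (i in seq_len(n)) {
      v <- tracks[[t]][[as.character(positions$chrom[i])]]
      if (!is.null(v) && bins[i] <= length(v)) X[i, t] <- v[bins[i]]
    }
  }
  missing <- apply(X, 1L, anyNA)
  if (any(missing)) {
    warning(sum(missing), " position(s) outside track bounds scored as NA")
  }
  score <- rep(NA_real_, n)
  if (any(!missing)) {
    score[!missing] <- predict(fit, X[!missing, , drop = FALSE])
  }
  data.frame(chrom = positions$chrom, pos = positions$pos, score = score)
}

#' Export per-position disease scores as 25 bp BED intervals
#'
#' Writes `chrom`, `start`, `end`, `score` with 0-based half-open
#' coordinates snapped to the 25 bp bin containing each position
#' (`start = floor((pos - 1) / 25) * 25`, `end = start + 25`).
#'
#' @param scored Output of [score_positions()].
#' @param file Output path (tab-separated, no header, BED-style).
#' @export
write_score_bed <- function(scored, file) {
  start0 <- (position_to_bin(scored$pos) - 1L) * track_bin_size
  bed <- data.frame(chrom = scored$chrom, start = start0,
                    end = start0 + track_bin_size, score = scored$score)
  bed <- bed[!is.na(bed$score), , drop = FALSE]
  write.table(bed, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}
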