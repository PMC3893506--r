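#' Extract promoter sequences around annotated TSS records
#'
#' The promoter window is -2000 bp to +500 bp around the transcription
#' start site in transcription direction: for a + strand TSS at 0-based
#' position t, the 0-based half-open region [t-2000, t+500); for a - strand
#' TSS, [t-499, t+2001) reverse-complemented so the returned string reads
#' 5' to 3' with the 2000 upstream bases first. Windows are truncated at
#' contig bounds.
#'
#' @param genome Named character vector or \code{DNAStringSet} of contigs.
#' @param tss_records BED6-style \code{data.frame} (\code{chrom},
#'   \code{start}, \code{end}, \code{name}, \code{score}, \code{strand};
#'   0-based half-open) or a \code{GRanges} of width-1 TSS positions.
#' @param upstream,downstream Window extents in bases (defaults 2000, 500).
#' @return A named \code{DNAStringSet} of promoter sequences (names are the
#'   record names / gene ids).
#' @export
extract_promoters <- function(genome, tss_records, upstream = 2000L,
                              downstream = 500L) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (methods::is(tss_records, "GRanges")) {
    gr <- tss_records
    nm <- names(gr) %||% S4Vectors::mcols(gr)$name
  } else {
    df <- tss_records
    miss <- setdiff(unique(df$chrom), names(genome))
    if (length(miss))
      abort_input("chromosome(s) absent from genome: ",
                  paste(miss, collapse = ", "),
                  " (records: ",
                  paste(df$name[df$chrom %in% miss], collapse = ", "), ")")
    if (any(!df$strand %in% c("+", "-")))
      abort_input("invalid strand for record(s): ",
                  paste(df$name[!df$strand %in% c("+", "-")], collapse = ", "))
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1L, width = 1L),
      strand = df$strand,
      seqlengths = setNames(Biostrings::width(genome), names(genome)))
    nm <- df$name
  }
  miss <- setdiff(as.character(GenomeInfoDb::seqnames(gr)), names(genome))
  if (length(miss))
    abort_input("chromosome(s) absent from genome: ",
                paste(miss, collapse = ", "))
  # out-of-bound windows are expected at contig edges; trim() truncates
  prom <- suppressWarnings(GenomicRanges::trim(
    GenomicRanges::promoters(gr, upstream = upstream,
                             downstream = downstream)))
  out <- Biostrings::DNAStringSet(vapply(seq_along(prom), function(i) {
    chrom <- as.character(GenomeInfoDb::seqnames(prom)[i])
    s <- Biostrings::subseq(genome[[chrom]],
                            start = GenomicRanges::start(prom)[i],
                            end = GenomicRanges::end(prom)[i])
    if (as.character(GenomicRanges::strand(prom)[i]) == "-")
      s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1L)))
  names(out) <- nm
  out
}

#' Build a position weight matrix from base counts
#'
#' \code{weight(b, j) = (count(b, j) + pseudocount) /
#' (colsum(j) + 4 * pseudocount)}; the maximum and minimum attainable
#' window scores (sums of per-position column maxima / minima) are cached
#' for threshold interpolation.
#'
#' @param counts 4 x width nonnegative matrix, rows A, C, G, T.
#' @param pseudocount Laplace pseudocount (default 1).
#' @param id Matrix identifier.
#' @return A list of class \code{"pwm"} with \code{id}, \code{counts},
#'   \code{weights}, \code{width}, \code{max_score}, \code{min_score}.
#' @export
pwm_from_counts <- function(counts, pseudocount = 1, id = "pwm") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || ncol(counts) < 1L)
    abort_input("counts must be a 4 x width matrix")
  if (any(counts < 0)) abort_input("counts must be nonnegative")
  if (any(colSums(counts) == 0) && pseudocount == 0)
    abort_input("zero column sum with zero pseudocount")
  rownames(counts) <- c("A", "C", "G", "T")
  w <- sweep(counts + pseudocount, 2L, colSums(counts) + 4 * pseudocount, "/")
  structure(list(id = id, counts = counts, weights = w,
                 width = ncol(counts),
                 max_score = sum(apply(w, 2L, max)),
                 min_score = sum(apply(w, 2L, min))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, score range [%.3f, %.3f]\n",
              x$id, x$width, x$min_score, x$max_score))
  invisible(x)
}

#' Read / write JASPAR-style PFM text
#'
#' The text format is a \code{>} header per matrix followed by four count
#' rows \code{A [ 3 5 ... ]} etc.
#'
#' @param path File path.
#' @param pseudocount Pseudocount forwarded to
#'   \code{\link{pwm_from_counts}}.
#' @return \code{read_pfms} returns a list of \code{"pwm"} objects.
#' @export
read_pfms <- function(path, pseudocount = 1) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  lapply(seq_along(heads), function(i) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    block <- lines[(heads[i] + 1L):(heads[i] + 4L)]
    counts <- t(vapply(block, function(l) {
      nums <- gsub("[][A-Za-z]", " ", l)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1L]])
    }, numeric(nchar_counts(block[1L]))))
    pwm_from_counts(counts, pseudocount = pseudocount, id = id)
  })
}

nchar_counts <- function(line) {
  nums <- gsub("[][A-Za-z]", " ", line)
  length(strsplit(trimws(nums), "\\s+")[[1L]])
}

#' @rdname read_pfms
#' @param pwms List of \code{"pwm"} objects.
#' @export
write_pfms <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$id),
      vapply(rownames(p$counts), function(b)
        sprintf("%s [ %s ]", b, paste(p$counts[b, ], collapse = " ")),
        character(1L)))
  }))
  writeLines(lines %||% character(), path)
  invisible(path)
}

# integer codes 1..4 for A,C,G,T; NA for anything else (N etc.)
dna_codes <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "")[[1L]],
        c("A", "C", "G", "T"))
}

scan_one_strand <- function(codes, w) {
  width <- ncol(w)
  L <- length(codes)
  if (L < width) return(numeric(0))
  n_win <- L - width + 1L
  scores <- numeric(n_win)
  for (j in seq_len(width)) {
    cj <- codes[j:(j + n_win - 1L)]
    scores <- scores + w[cbind(cj, j)]    # NA codes poison the window
  }
  scores
}

#' Scan a sequence with a position weight matrix
#'
#' Every window of the PWM's width is scored as the sum of per-position
#' weights for its bases; a window matches when its score reaches the
#' threshold. The default threshold convention interpolates the score
#' range: \code{min_score + fraction * (max_score - min_score)}; the
#' alternative \code{"max"} convention uses \code{fraction * max_score}.
#' Windows containing any non-ACGT base are skipped. With
#' \code{both_strands} the reverse complement is scanned too and counts
#' summed; overlapping matches all count.
#'
#' @param seq DNA string (character or \code{DNAString}).
#' @param pwm A \code{"pwm"}.
#' @param min_score_fraction Match threshold fraction in (0, 1]
#'   (default 0.9).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @param convention \code{"minmax"} (default) or \code{"max"}.
#' @return A list with \code{count} and a \code{positions}
#'   \code{data.frame} (\code{start} of the window on the given strand's
#'   coordinates, \code{strand}, \code{score}).
#' @export
scan_pwm <- function(seq, pwm, min_score_fraction = 0.9, both_strands = TRUE,
                     convention = c("minmax", "max")) {
  convention <- match.arg(convention)
  if (!(min_score_fraction > 0 && min_score_fraction <= 1))
    abort_input("min_score_fraction must be in (0, 1]")
  thr <- if (convention == "minmax")
    pwm$min_score + min_score_fraction * (pwm$max_score - pwm$min_score)
  else min_score_fraction * pwm$max_score
  seq_chr <- as.character(seq)
  hits <- function(s, strand) {
    sc <- scan_one_strand(dna_codes(s), pwm$weights)
    ok <- which(!is.na(sc) & sc >= thr)
    data.frame(start = ok, strand = rep(strand, length(ok)), score = sc[ok],
               stringsAsFactors = FALSE)
  }
  pos <- hits(seq_chr, "+")
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq_chr)))
    pos <- rbind(pos, hits(rc, "-"))
  }
  list(count = nrow(pos), positions = pos)
}

#' Match-count matrix of promoters against a PWM collection
#'
#' @param promoters Named \code{DNAStringSet} (or character vector) of
#'   promoter sequences; names must be unique gene ids.
#' @param pwms List of \code{"pwm"} objects.
#' @param min_score_fraction,both_strands,convention Forwarded to
#'   \code{\link{scan_pwm}}.
#' @return Integer matrix, genes x matrices, of match counts.
#' @export
tfbs_profile_matrix <- function(promoters, pwms, min_score_fraction = 0.9,
                                both_strands = TRUE,
                                convention = c("minmax", "max")) {
  convention <- match.arg(convention)
  ids <- names(promoters)
  if (is.null(ids) || anyDuplicated(ids))
    abort_input("promoters need unique gene-id names")
  seqs <- as.character(promoters)
  out <- matrix(0L, length(seqs), length(pwms),
                dimnames = list(ids, vapply(pwms, `[[`, "", "id")))
  for (j in seq_along(pwms)) {
    out[, j] <- vapply(seqs, function(s)
      scan_pwm(s, pwms[[j]], min_score_fraction, both_strands,
               convention)$count, integer(1L))
  }
  out
}

#' Jaccard similarity of promoter binding-site content
#'
#' On binarized presence profiles, \code{J = |P1 n P2| / |P1 u P2|}: joint
#' absence of a matrix contributes nothing to similarity. The diagonal is
#' 1; a gene with an empty presence set scores 0 against every other gene.
#' The count-weighted variant uses \code{sum(min) / sum(max)} over raw
#' counts.
#'
#' @param profile Genes x matrices count (or logical) matrix.
#' @param weighted Use the count-weighted Jaccard (default FALSE).
#' @return Symmetric genes x genes similarity matrix in [0, 1].
#' @export
jaccard_matrix <- function(profile, weighted = FALSE) {
  m <- as.matrix(profile)
  n <- nrow(m)
  if (weighted) {
    sim <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i) {
      mx <- sum(pmax(m[i, ], m[j, ]))
      s <- if (mx == 0) 0 else sum(pmin(m[i, ], m[j, ])) / mx
      sim[i, j] <- sim[j, i] <- s
    }
    return(sim)
  }
  b <- (m > 0) * 1
  inter <- tcrossprod(b)
  sizes <- rowSums(b)
  uni <- outer(sizes, sizes, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(m), rownames(m))
  sim
}
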