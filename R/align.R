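#' Build a C-to-T converted alignment index
#'
#' Bisulfite conversion collapses C and T, so alignment is done in three-letter
#' space: every reference sequence is C-to-T converted and indexed by exact
#' k-mers (the seeds). Original sequences are retained so that methylation
#' evidence can later be read off the unconverted reference.
#'
#' @param reference named character vector of sense-strand transcript
#'   sequences.
#' @param seed_len seed k-mer length (nt). Seeds are matched exactly,
#'   mirroring a zero-mismatch seed policy.
#' @return object of class `bisulfite_index`.
#' @export
build_converted_index <- function(reference, seed_len = 25L) {
  if (length(reference) == 0L) stop("empty reference")
  if (is.null(names(reference)) || anyDuplicated(names(reference)))
    stop("reference sequences must have unique ids")
  reference <- toupper(reference)
  converted <- chartr("C", "T", reference)
  kmers <- data.table::rbindlist(lapply(seq_along(converted), function(i) {
    s <- converted[[i]]
    L <- nchar(s)
    if (L < seed_len) return(NULL)
    pos <- seq_len(L - seed_len + 1L)
    data.table::data.table(kmer = substring(s, pos, pos + seed_len - 1L),
                           tid = i, pos = pos)
  }))
  data.table::setkey(kmers, kmer)
  structure(list(reference = reference, converted = converted,
                 kmers = kmers, seed_len = as.integer(seed_len)),
            class = "bisulfite_index")
}

#' @export
print.bisulfite_index <- function(x, ...) {
  cat(sprintf("<bisulfite_index> %d sequences, %d seed k-mers (k=%d)\n",
              length(x$reference), nrow(x$kmers), x$seed_len))
  invisible(x)
}

n_mismatch <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# candidate loci for a converted read: seed lookup + full verification
candidate_loci <- function(index, read_ct, max_mismatch) {
  k <- index$seed_len
  if (nchar(read_ct) < k) return(NULL)
  seed <- substr(read_ct, 1L, k)
  hits <- index$kmers[data.table::J(seed), nomatch = NULL]
  if (!nrow(hits)) return(NULL)
  len <- nchar(read_ct)
  keep <- logical(nrow(hits)); mm <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    refct <- index$converted[[hits$tid[i]]]
    p <- hits$pos[i]
    if (p + len - 1L > nchar(refct)) next
    m <- n_mismatch(read_ct, substr(refct, p, p + len - 1L))
    if (m <= max_mismatch) { keep[i] <- TRUE; mm[i] <- m }
  }
  if (!any(keep)) return(NULL)
  out <- hits[keep]
  out$mm <- mm[keep]
  out
}

#' Align one bisulfite read pair
#'
#' Read 1 is C-to-T converted and matched against the converted index with an
#' exact seed; candidate loci are verified in converted space allowing at most
#' `max_mismatch` mismatches over the full read. Ties between distinct loci
#' are rejected as ambiguous (only unique alignments are ever emitted). The
#' mate must map concordantly on the same transcript with fragment span at
#' most `max_insert`. Methylation evidence (`ref_c_positions`, `read_c_mask`)
#' is taken from the original read against the original reference.
#'
#' @param index a [build_converted_index()] object.
#' @param r1,r2 read sequences (read 2 is the reverse complement of the
#'   fragment 3' end).
#' @param read_id read identifier.
#' @param max_mismatch maximum converted-space mismatches per read.
#' @param max_insert maximum fragment span in nt (mate distance gate).
#' @return list of class `alignment_record`, or of class `alignment_rejection`
#'   with a `reason` in `ambiguous`, `unmapped`, `discordant_mate`,
#'   `too_short`.
#' @export
align_read_pair <- function(index, r1, r2, read_id = "read",
                            max_mismatch = 2L, max_insert = 500L) {
  if (is.na(r1) || is.na(r2) || !nzchar(r1) || !nzchar(r2))
    stop("malformed FASTQ record for read ", read_id)
  r1 <- toupper(r1); r2 <- toupper(r2)
  if (grepl("[^ACGTN]", r1) || grepl("[^ACGTN]", r2))
    stop("malformed FASTQ record for read ", read_id)
  if (nchar(r1) < index$seed_len)
    return(rejection(read_id, "too_short"))
  cand <- candidate_loci(index, chartr("C", "T", r1), max_mismatch)
  if (is.null(cand)) return(rejection(read_id, "unmapped"))
  best <- min(cand$mm)
  cand <- cand[cand$mm == best, ]
  cand <- unique(cand, by = c("tid", "pos"))
  if (nrow(cand) > 1L) return(rejection(read_id, "ambiguous"))
  tid <- cand$tid[1]; p1 <- cand$pos[1]   # 1-based on transcript
  # concordant mate: revcomp(read2) is converted fragment-end sense sequence
  mate_ct <- chartr("C", "T", revcomp(r2))
  if (!mate_concordant(index, mate_ct, tid, p1, max_mismatch, max_insert))
    return(rejection(read_id, "discordant_mate"))
  # methylation evidence from ORIGINAL reference vs ORIGINAL read 1
  ref <- index$reference[[tid]]
  len1 <- nchar(r1)
  window <- substr(ref, p1, p1 + len1 - 1L)
  wc <- strsplit(window, "")[[1]]
  rc <- strsplit(r1, "")[[1]]
  cpos <- which(wc == "C")
  structure(list(read_id = read_id,
                 transcript_id = names(index$reference)[tid],
                 tpos = p1 - 1L,                 # 0-based start
                 length = len1,
                 ref_c_positions = p1 - 1L + cpos - 1L,  # 0-based offsets
                 read_c_mask = rc[cpos] == "C",
                 read_c_base = rc[cpos],
                 n_mismatch_non_c = best),
            class = "alignment_record")
}

rejection <- function(read_id, reason) {
  structure(list(read_id = read_id, reason = reason),
            class = "alignment_rejection")
}

# verify mate concordance: seed lookup first, linear scan as fallback
mate_concordant <- function(index, mate_ct, tid, p1, max_mismatch,
                            max_insert) {
  len2 <- nchar(mate_ct)
  refct <- index$converted[[tid]]
  lo <- p1
  hi <- min(nchar(refct) - len2 + 1L, p1 + max_insert - len2)
  if (hi < lo) return(FALSE)
  if (len2 >= index$seed_len) {
    seed <- substr(mate_ct, 1L, index$seed_len)
    hits <- index$kmers[data.table::J(seed), nomatch = NULL]
    hits <- hits[hits$tid == tid & hits$pos >= lo & hits$pos <= hi, ]
    for (p2 in hits$pos) {
      if (n_mismatch(mate_ct, substr(refct, p2, p2 + len2 - 1L)) <=
          max_mismatch) return(TRUE)
    }
  }
  # fallback scan (covers seeds hit by sequencing errors)
  for (p2 in lo:hi) {
    if (n_mismatch(mate_ct, substr(refct, p2, p2 + len2 - 1L)) <=
        max_mismatch) return(TRUE)
  }
  FALSE
}

#' Align a set of read pairs
#'
#' Batch equivalent of [align_read_pair()]: one seed lookup over all reads,
#' then per-candidate verification. Returns per-read alignment rows, a long
#' table of per-cytosine observations (the input to pileups), and the rejected
#' reads with reasons. Only read 1 contributes cytosine observations: one
#' observation per fragment avoids double-counting overlapping mates.
#'
#' @param index a [build_converted_index()] object.
#' @param read1,read2 named character vectors of read sequences (as from
#'   [read_fastq()]), or paths to FASTQ files.
#' @param max_mismatch,max_insert see [align_read_pair()].
#' @return list of class `bisseq_alignments` with data.frames `alignments`
#'   (read_id, transcript_id, tpos, length, c_total, c_unconverted,
#'   n_mismatch_non_c), `observations` (read_id, transcript_id, tpos,
#'   read_base), and `rejected` (read_id, reason).
#' @export
align_reads <- function(index, read1, read2, max_mismatch = 2L,
                        max_insert = 500L) {
  if (length(read1) == 1L && file.exists(read1)) read1 <- read_fastq(read1)
  if (length(read2) == 1L && file.exists(read2)) read2 <- read_fastq(read2)
  stopifnot(length(read1) == length(read2))
  n <- length(read1)
  ids <- names(read1)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))
  r1 <- toupper(unname(read1)); r2 <- toupper(unname(read2))
  bad <- is.na(r1) | is.na(r2) | grepl("[^ACGTN]", r1) | grepl("[^ACGTN]", r2)
  if (any(bad)) stop("malformed FASTQ record for read ", ids[which(bad)[1]])
  k <- index$seed_len
  r1ct <- chartr("C", "T", r1)
  mate_ct <- chartr("C", "T", revcomp(r2))
  status <- rep("unmapped", n)
  tid <- integer(n); p1 <- integer(n); mmv <- integer(n)
  status[nchar(r1) < k] <- "too_short"
  ok <- which(status == "unmapped")
  # one keyed join for all seeds
  seeds <- data.table::data.table(kmer = substr(r1ct[ok], 1L, k), read = ok)
  hits <- index$kmers[seeds, on = "kmer", nomatch = NULL,
                      allow.cartesian = TRUE]
  lens <- nchar(r1)
  if (nrow(hits)) {
    by_read <- split(seq_len(nrow(hits)), hits$read)
    for (rd in names(by_read)) {
      i <- as.integer(rd)
      rows <- by_read[[rd]]
      len <- lens[i]
      best_mm <- max_mismatch + 1L
      best <- NULL; tie <- FALSE
      for (h in rows) {
        ht <- hits$tid[h]; hp <- hits$pos[h]
        refct <- index$converted[[ht]]
        if (hp + len - 1L > nchar(refct)) next
        m <- n_mismatch(r1ct[i], substr(refct, hp, hp + len - 1L))
        if (m < best_mm) {
          best_mm <- m; best <- c(ht, hp); tie <- FALSE
        } else if (m == best_mm && !is.null(best) &&
                   !(best[1] == ht && best[2] == hp)) {
          tie <- TRUE
        }
      }
      if (is.null(best)) next
      if (tie) { status[i] <- "ambiguous"; next }
      if (!mate_concordant(index, mate_ct[i], best[1], best[2],
                           max_mismatch, max_insert)) {
        status[i] <- "discordant_mate"; next
      }
      status[i] <- "aligned"
      tid[i] <- best[1]; p1[i] <- best[2]; mmv[i] <- best_mm
    }
  }
  al <- which(status == "aligned")
  # methylation evidence from the original read vs original reference
  c_total <- integer(length(al)); c_unconv <- integer(length(al))
  obs_id <- vector("list", length(al))
  obs_tid <- vector("list", length(al))
  obs_pos <- vector("list", length(al))
  obs_base <- vector("list", length(al))
  for (q in seq_along(al)) {
    i <- al[q]
    window <- substr(index$reference[[tid[i]]], p1[i], p1[i] + lens[i] - 1L)
    wc <- strsplit(window, "")[[1]]
    cpos <- which(wc == "C")
    c_total[q] <- length(cpos)
    if (length(cpos)) {
      rb <- strsplit(r1[i], "")[[1]][cpos]
      c_unconv[q] <- sum(rb == "C")
      obs_id[[q]] <- rep(ids[i], length(cpos))
      obs_tid[[q]] <- rep(names(index$reference)[tid[i]], length(cpos))
      obs_pos[[q]] <- p1[i] - 1L + cpos - 1L
      obs_base[[q]] <- rb
    }
  }
  alignments <- data.frame(
    read_id = ids[al],
    transcript_id = names(index$reference)[tid[al]],
    tpos = p1[al] - 1L, length = lens[al],
    c_total = c_total, c_unconverted = c_unconv,
    n_mismatch_non_c = mmv[al], stringsAsFactors = FALSE)
  observations <- data.frame(
    read_id = unlist(obs_id) %||% character(),
    transcript_id = unlist(obs_tid) %||% character(),
    tpos = unlist(obs_pos) %||% integer(),
    read_base = unlist(obs_base) %||% character(),
    stringsAsFactors = FALSE)
  rej <- which(status != "aligned")
  rejected <- data.frame(read_id = ids[rej], reason = status[rej],
                         stringsAsFactors = FALSE)
  structure(list(alignments = alignments, observations = observations,
                 rejected = rejected),
            class = "bisseq_alignments")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bisseq_alignments <- function(x, ...) {
  cat(sprintf("<bisseq_alignments> %d aligned, %d rejected\n",
              nrow(x$alignments), nrow(x$rejected)))
  if (nrow(x$rejected))
    print(table(x$rejected$reason))
  invisible(x)
}

#' Write alignments as TSV
#' @param aln a `bisseq_alignments` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  utils::write.table(aln$alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
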