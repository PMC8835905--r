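# Read-level processing: FASTQ input, trimming/filtering, classification.

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (plain or gzip).
#' @return Data frame with columns `id`, `seq` (upper-case DNA), `qual`.
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) {
      stop(sprintf("malformed FASTQ '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  data.frame(
    id = sub("\\s.*$", "", names(x)),
    seq = toupper(as.character(x)),
    qual = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE
  )
}

# Character matrix of reads indexed [read, position-from-end]; NA past the
# 5' end. Used for suffix-anchored adapter matching.
chars_from_end <- function(seq, L) {
  n <- length(seq)
  lens <- nchar(seq)
  m <- matrix(NA_character_, n, L)
  if (n == 0L || max(lens) == 0L) return(m)
  row <- rep(seq_len(n), lens)
  pos <- sequence(lens)
  d <- lens[row] - pos + 1L
  keep <- d <= L
  m[cbind(row[keep], d[keep])] <-
    unlist(strsplit(seq, "", fixed = TRUE))[keep]
  m
}

# Leftmost internal full-adapter match with <= allowed mismatches; returns
# the 1-based match start per read (NA if none). Exact matches are found
# with a vectorised fixed-string search; the mismatch-tolerant scan only
# visits reads without an exact hit.
locate_adapter_full <- function(seq, adapter, allowed) {
  n <- length(seq)
  pos <- regexpr(adapter, seq, fixed = TRUE)
  pos <- ifelse(pos > 0, as.integer(pos), NA_integer_)
  if (allowed > 0L && anyNA(pos)) {
    todo <- which(is.na(pos))
    a <- strsplit(adapter, "", fixed = TRUE)[[1]]
    alen <- length(a)
    for (i in todo) {
      s_chars <- strsplit(seq[i], "", fixed = TRUE)[[1]]
      L <- length(s_chars)
      if (L < alen) next
      for (s in seq_len(L - alen + 1L)) {
        if (sum(s_chars[s:(s + alen - 1L)] != a) <= allowed) {
          pos[i] <- s
          break
        }
      }
    }
  }
  pos
}

# Leftmost suffix-anchored partial-adapter match (overlap o in
# [min_overlap, alen - 1], <= 10% mismatches); returns match start or NA.
locate_adapter_suffix <- function(seq, adapter, min_overlap = 3L,
                                  mismatch_rate = 0.1) {
  n <- length(seq)
  lens <- nchar(seq)
  a <- strsplit(adapter, "", fixed = TRUE)[[1]]
  alen <- length(a)
  o_max <- min(alen - 1L, max(lens, 0L))
  pos <- rep(NA_integer_, n)
  if (n == 0L || o_max < min_overlap) return(pos)
  em <- chars_from_end(seq, o_max)
  for (o in seq(o_max, min_overlap)) {  # largest overlap = leftmost start
    open <- is.na(pos) & lens >= o
    if (!any(open)) next
    mm <- integer(n)
    for (k in seq_len(o)) mm <- mm + (em[, k] != a[o - k + 1L])
    hit <- open & !is.na(mm) & mm <= floor(mismatch_rate * o)
    pos[hit] <- lens[hit] - o + 1L
  }
  pos
}

#' Trim adapters and quality-filter small RNA reads
#'
#' Processing order per read: (1) 3' quality trimming (cutadapt-style
#' partial-sum algorithm at cutoff `min_q`); (2) adapter removal at the
#' leftmost match, where a match is either the full adapter anywhere in the
#' read with at most 10% mismatches, or a prefix of the adapter anchored at
#' the read's 3' end with at least `min_overlap` nt overlap and at most 10%
#' mismatches — everything from the match start on is removed; (3) length
#' filtering: reads shorter than `min_len` (default 17 nt) or longer than
#' `max_len` (default 30 nt) after trimming are discarded. Reads without
#' any adapter occurrence are kept untrimmed if within the length bounds.
#'
#' @param reads Read table (`id`, `seq`, `qual`) from [read_fastq()] or a
#'   FASTQ path.
#' @param adapter 3' adapter DNA sequence.
#' @param min_len,max_len Retained insert length bounds in nt.
#' @param min_q Phred cutoff for 3' quality trimming (default 20).
#' @param min_overlap Minimum adapter overlap at the read end (default 3).
#' @param qual_offset Phred ASCII offset (default 33).
#' @return List with `reads` (surviving read table, trimmed) and `stats`
#'   (named list: `n_in`, `n_quality_trimmed`, `n_adapter_trimmed`,
#'   `n_too_short`, `n_too_long`, `n_out`).
#' @export
trim_and_filter <- function(reads, adapter, min_len = 17L, max_len = 30L,
                            min_q = 20L, min_overlap = 3L,
                            qual_offset = 33L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(is.data.frame(reads),
            all(c("id", "seq", "qual") %in% names(reads)))
  if (!nzchar(adapter)) stop("'adapter' must be non-empty", call. = FALSE)
  if (min_len > max_len) stop("min_len must be <= max_len", call. = FALSE)
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad)) {
    stop(sprintf("malformed read record '%s': sequence and quality lengths differ",
                 reads$id[bad[1]]), call. = FALSE)
  }
  adapter <- toupper(adapter)
  n <- nrow(reads)
  seq <- toupper(reads$seq)
  qual <- reads$qual
  lens <- nchar(seq)
  stats <- list(n_in = n, n_quality_trimmed = 0L, n_adapter_trimmed = 0L,
                n_too_short = 0L, n_too_long = 0L, n_out = 0L)
  if (n == 0L) {
    return(list(reads = reads[0, ], stats = stats))
  }

  # --- 3' quality trimming (partial sums from the read end) ---
  L <- max(lens)
  qm <- matrix(NA_integer_, n, L)
  row <- rep(seq_len(n), lens)
  pos <- sequence(lens)
  allq <- utf8ToInt(paste(qual, collapse = "")) - qual_offset
  qm[cbind(row, lens[row] - pos + 1L)] <- allq
  run <- numeric(n); best <- numeric(n); bestd <- integer(n)
  for (d in seq_len(L)) {
    s <- min_q - qm[, d]
    act <- !is.na(s)
    if (!any(act)) break
    run[act] <- run[act] + s[act]
    upd <- act & run > best
    best[upd] <- run[upd]
    bestd[upd] <- d
  }
  stats$n_quality_trimmed <- sum(bestd > 0L)
  lens <- lens - bestd
  seq <- substring(seq, 1L, lens)
  qual <- substring(qual, 1L, lens)

  # --- adapter removal ---
  allowed_full <- floor(0.1 * nchar(adapter))
  posA <- locate_adapter_full(seq, adapter, allowed_full)
  posB <- locate_adapter_suffix(seq, adapter, min_overlap = min_overlap)
  cut <- pmin(posA, posB, na.rm = TRUE)
  cut[is.na(posA) & is.na(posB)] <- NA_integer_
  hit <- !is.na(cut)
  stats$n_adapter_trimmed <- sum(hit)
  lens[hit] <- cut[hit] - 1L
  seq <- substring(seq, 1L, lens)
  qual <- substring(qual, 1L, lens)

  # --- length filter ---
  short <- lens < min_len
  long <- lens > max_len
  stats$n_too_short <- sum(short)
  stats$n_too_long <- sum(long)
  keep <- !short & !long
  stats$n_out <- sum(keep)
  out <- data.frame(id = reads$id[keep], seq = seq[keep], qual = qual[keep],
                    stringsAsFactors = FALSE)
  list(reads = out, stats = stats)
}

# Precompute lookup tables for exact (0-mismatch) mature matching at 3'
# length offsets 0..len_tol. Returns an environment used by classify_reads.
build_mature_index <- function(refs_dna, len_tol) {
  idx <- list()
  lens <- nchar(refs_dna)
  for (t in 0:len_tol) {
    keys <- substr(refs_dna, 1L, lens - t)
    keep <- nchar(keys) > 0L
    idx[[paste0("trim", t)]] <- list(
      key = keys[keep], name = names(refs_dna)[keep],
      dup = keys[keep] %in% keys[keep][duplicated(keys[keep])]
    )
  }
  idx$full <- list(key = unname(refs_dna), name = names(refs_dna),
                   dup = refs_dna %in% refs_dna[duplicated(refs_dna)])
  idx
}

#' Classify trimmed reads against spike-in cores and mature miRNAs
#'
#' Spike-ins take precedence: a read containing any panel core verbatim
#' (0 mismatches, any offset) is assigned that oligo's label — the core is
#' the oligo's only identity since its flanks are random. Otherwise the
#' read is matched 5'-anchored and gap-free against the mature reference
#' sequences, tolerating up to `max_mismatch` substitutions over the
#' overlapping prefix and a 3' length difference of up to `len_tol` nt in
#' either direction (the dominant isomiR mode). Hits are ranked by
#' (mismatches, |length difference|); ambiguous equal-best hits resolve to
#' the lexicographically smallest miRNA name and are flagged. Unmatched
#' reads fall into `"unmapped"`.
#'
#' @param seqs Character vector of trimmed read sequences (DNA).
#' @param panel A `spike_panel`.
#' @param mirna_refs Named character vector of mature sequences (RNA or
#'   DNA) or FASTA path.
#' @param max_mismatch Maximum substitutions against a mature sequence
#'   (default 1).
#' @param len_tol Maximum 3' length difference in nt (default 2).
#' @return Data frame with columns `feature`, `class`
#'   (`spike`/`mirna`/`unmapped`) and `ambiguous`.
#' @export
classify_reads <- function(seqs, panel, mirna_refs, max_mismatch = 1L,
                           len_tol = 2L) {
  stopifnot(inherits(panel, "spike_panel"))
  if (is.character(mirna_refs) && length(mirna_refs) == 1L &&
      file.exists(mirna_refs) && is.null(names(mirna_refs))) {
    mirna_refs <- read_mature_refs(mirna_refs)
  }
  refs_dna <- rna_to_dna(mirna_refs)
  refs_dna <- refs_dna[order(names(refs_dna))]  # lexicographic tie-break
  seqs <- toupper(seqs)
  n <- length(seqs)
  feature <- rep(NA_character_, n)
  ambiguous <- rep(FALSE, n)

  # spike-ins first (exact core containment, panel order)
  cores_dna <- rna_to_dna(panel$core)
  open <- rep(TRUE, n)
  for (i in seq_along(cores_dna)) {
    hit <- open & grepl(cores_dna[i], seqs, fixed = TRUE)
    feature[hit] <- panel$label[i]
    open <- open & !hit
  }

  if (any(open) && length(refs_dna)) {
    idx <- build_mature_index(refs_dna, len_tol)
    lens <- nchar(seqs)
    # exact stages in order of |length difference|
    for (t in 0:len_tol) {
      todo <- which(open)
      if (!length(todo)) break
      # read shorter than (or equal to) the mature by t nt
      tab <- idx[[paste0("trim", t)]]
      m <- match(seqs[todo], tab$key)
      hit_short <- !is.na(m)
      # read longer than the mature by t nt
      if (t > 0L) {
        pre <- substr(seqs[todo], 1L, pmax(lens[todo] - t, 0L))
        m2 <- match(pre, idx$full$key)
        hit_long <- !is.na(m2)
      } else {
        m2 <- rep(NA_integer_, length(todo))
        hit_long <- rep(FALSE, length(todo))
      }
      hit <- hit_short | hit_long
      if (!any(hit)) next
      name_s <- ifelse(hit_short, tab$name[m], NA_character_)
      name_l <- ifelse(hit_long, idx$full$name[m2], NA_character_)
      amb <- (hit_short & tab$dup[ifelse(hit_short, m, 1L)]) |
        (hit_long & idx$full$dup[ifelse(hit_long, m2, 1L)]) |
        (hit_short & hit_long & name_s != name_l)
      nm <- pmin(name_s, name_l, na.rm = TRUE)
      feature[todo[hit]] <- nm[hit]
      ambiguous[todo[hit]] <- amb[hit]
      open[todo[hit]] <- FALSE
    }
    # mismatch-tolerant fallback, per read
    if (max_mismatch > 0L && any(open)) {
      ref_ints <- lapply(refs_dna, utf8ToInt)
      ref_lens <- nchar(refs_dna)
      for (i in which(open)) {
        ri <- utf8ToInt(seqs[i])
        Lr <- length(ri)
        cand <- which(abs(ref_lens - Lr) <= len_tol)
        if (!length(cand)) next
        best_mm <- Inf; best_d <- Inf; best_names <- character(0)
        for (j in cand) {
          ov <- min(Lr, ref_lens[j])
          mm <- sum(ri[seq_len(ov)] != ref_ints[[j]][seq_len(ov)])
          if (mm > max_mismatch) next
          dd <- abs(ref_lens[j] - Lr)
          if (mm < best_mm || (mm == best_mm && dd < best_d)) {
            best_mm <- mm; best_d <- dd
            best_names <- names(refs_dna)[j]
          } else if (mm == best_mm && dd == best_d) {
            best_names <- c(best_names, names(refs_dna)[j])
          }
        }
        if (length(best_names)) {
          feature[i] <- min(best_names)
          ambiguous[i] <- length(best_names) > 1L
        }
      }
    }
  }

  cls <- ifelse(is.na(feature), "unmapped",
                ifelse(feature %in% panel$label, "spike", "mirna"))
  feature[is.na(feature)] <- "unmapped"
  data.frame(feature = feature, class = cls, ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

#' @rdname classify_reads
#' @param seq A single trimmed read sequence.
#' @return `classify_read()` returns the assigned feature id (a spike-in
#'   label, a miRNA name, or `"unmapped"`).
#' @export
classify_read <- function(seq, panel, mirna_refs, max_mismatch = 1L,
                          len_tol = 2L) {
  classify_reads(seq, panel, mirna_refs, max_mismatch = max_mismatch,
                 len_tol = len_tol)$feature
}

#' Count reads per feature across samples
#'
#' Runs [trim_and_filter()] and [classify_reads()] on every sample and
#' assembles the feature-by-sample count matrix. Every surviving read falls
#' in exactly one bin, so each column satisfies
#' `sum(spike) + sum(miRNA) + unmapped = surviving reads`.
#'
#' @param samples Named list; each element a FASTQ path or a read table
#'   (`id`, `seq`, `qual`).
#' @param panel A `spike_panel`.
#' @param mirna_refs Named character vector of mature sequences or FASTA
#'   path.
#' @param adapter 3' adapter sequence.
#' @param ... Further arguments to [trim_and_filter()] and
#'   [classify_reads()] (`min_len`, `max_len`, `min_q`, `max_mismatch`,
#'   `len_tol`).
#' @return Object of class `mind_counts`: list with `counts` (integer
#'   matrix, rows = spike labels, miRNA names, `"unmapped"`),
#'   `feature_class` (named vector `spike`/`mirna`/`unmapped`), and `stats`
#'   (per-sample data frame of read-fate tallies).
#' @export
count_samples <- function(samples, panel, mirna_refs, adapter,
                          min_len = 17L, max_len = 30L, min_q = 20L,
                          max_mismatch = 1L, len_tol = 2L) {
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("'samples' must be a named list", call. = FALSE)
  }
  if (anyDuplicated(names(samples))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (is.character(mirna_refs) && length(mirna_refs) == 1L &&
      file.exists(mirna_refs) && is.null(names(mirna_refs))) {
    mirna_refs <- read_mature_refs(mirna_refs)
  }
  features <- c(panel$label, names(mirna_refs), "unmapped")
  counts <- matrix(0L, nrow = length(features), ncol = length(samples),
                   dimnames = list(features, names(samples)))
  stats <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    tf <- trim_and_filter(samples[[k]], adapter = adapter,
                          min_len = min_len, max_len = max_len,
                          min_q = min_q)
    cl <- classify_reads(tf$reads$seq, panel, mirna_refs,
                         max_mismatch = max_mismatch, len_tol = len_tol)
    tab <- table(factor(cl$feature, levels = features))
    counts[, k] <- as.integer(tab)
    s <- tf$stats
    stats[[k]] <- data.frame(
      sample = names(samples)[k], reads_in = s$n_in,
      surviving = s$n_out, adapter_trimmed = s$n_adapter_trimmed,
      too_short = s$n_too_short, too_long = s$n_too_long,
      spike = sum(cl$class == "spike"), mirna = sum(cl$class == "mirna"),
      unmapped = sum(cl$class == "unmapped"),
      ambiguous = sum(cl$ambiguous),
      stringsAsFactors = FALSE
    )
  }
  structure(list(
    counts = counts,
    feature_class = stats::setNames(
      c(rep("spike", nrow(panel)), rep("mirna", length(mirna_refs)),
        "unmapped"), features),
    stats = do.call(rbind, stats)
  ), class = "mind_counts")
}

#' @export
print.mind_counts <- function(x, ...) {
  cat(sprintf("Count matrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  spike-in rows: %d, miRNA rows: %d\n",
              sum(x$feature_class == "spike"),
              sum(x$feature_class == "mirna")))
  print(x$stats, row.names = FALSE)
  invisible(x)
}
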