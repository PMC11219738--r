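# longest ATG-initiated ORF with an in-frame stop; returns NULL when none.
# Coordinates are 1-based transcript positions; `end` includes the stop codon.
longest_orf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 6) return(NULL)
  ch3 <- substring(s, seq_len(n - 2), seq_len(n - 2) + 2L)
  atg <- which(ch3 == "ATG")
  stp <- which(ch3 %in% c("TAA", "TAG", "TGA"))
  if (length(atg) == 0 || length(stp) == 0) return(NULL)
  best <- NULL
  for (f in 0:2) {
    a <- atg[atg %% 3 == (f + 1) %% 3]
    st <- stp[stp %% 3 == (f + 1) %% 3]
    if (length(a) == 0 || length(st) == 0) next
    # first stop strictly after each start
    idx <- findInterval(a, st) + 1L
    ok <- idx <= length(st)
    for (i in which(ok)) {
      len <- st[idx[i]] + 2L - a[i] + 1L
      if (is.null(best) || len > best$len ||
          (len == best$len && a[i] < best$start)) {
        best <- list(start = a[i], end = st[idx[i]] + 2L,
                     stop_start = st[idx[i]], len = len)
      }
    }
  }
  if (is.null(best)) return(NULL)
  cds <- substr(s, best$start, best$end)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  best$aa <- sub("\\*$", "", aa)
  best
}

#' Predict NMD sensitivity of a transcript
#'
#' Applies the 50-nt rule: a transcript is NMD-sensitive when its stop codon
#' (first base, transcript coordinates, from the longest ATG-initiated ORF or
#' a supplied CDS) lies at least 50 nt upstream of the last exon-exon
#' junction (the transcript coordinate of the final base of the penultimate
#' exon). Mono-exon transcripts are insensitive. A distance of exactly 50 nt
#' is sensitive.
#'
#' @param model exon table rows of one transcript.
#' @param genome named character vector (ignored when `tx_seq` given).
#' @param tx_seq optional precomputed transcript sequence.
#' @param orf_start optional 1-based transcript coordinate of the CDS start;
#'   when missing the longest ORF is used.
#' @param min_distance the PTC rule distance (nt).
#' @return one-row tibble: `nmd` (`"sensitive"`/`"insensitive"`),
#'   `stop_pos`, `last_junction_pos` (transcript coordinates; NA when no ORF
#'   or junction).
#' @export
predict_nmd <- function(model, genome = NULL, tx_seq = NULL, orf_start = NULL,
                        min_distance = 50L) {
  model <- arrange(model, .data$start)
  k <- nrow(model)
  if (is.null(tx_seq)) {
    stopifnot(!is.null(genome))
    tx_seq <- transcript_seq(model, genome)
  }
  if (k < 2) {
    return(tibble(nmd = "insensitive", stop_pos = NA_integer_,
                  last_junction_pos = NA_integer_))
  }
  widths <- model$end - model$start + 1
  # transcript coordinate of the last base of the penultimate exon
  if (model$strand[1] == "+") {
    last_junction <- sum(widths[seq_len(k - 1)])
  } else {
    last_junction <- sum(widths[k:2])
  }
  if (is.null(orf_start)) {
    orf <- longest_orf(tx_seq)
    if (is.null(orf)) {
      return(tibble(nmd = "insensitive", stop_pos = NA_integer_,
                    last_junction_pos = as.integer(last_junction)))
    }
    stop_pos <- orf$stop_start
  } else {
    # first in-frame stop from the given start
    n <- nchar(tx_seq)
    cods <- substring(tx_seq, seq(orf_start, n - 2, by = 3),
                      seq(orf_start, n - 2, by = 3) + 2)
    hit <- which(cods %in% c("TAA", "TAG", "TGA"))
    if (length(hit) == 0) {
      return(tibble(nmd = "insensitive", stop_pos = NA_integer_,
                    last_junction_pos = as.integer(last_junction)))
    }
    stop_pos <- orf_start + (hit[1] - 1) * 3
  }
  sensitive <- (last_junction - stop_pos) >= min_distance
  tibble(nmd = if (sensitive) "sensitive" else "insensitive",
         stop_pos = as.integer(stop_pos),
         last_junction_pos = as.integer(last_junction))
}
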