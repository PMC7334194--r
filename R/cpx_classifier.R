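#' Build a resolved alternate-allele structure
#'
#' A structure is an ordered set of segments, each with a source interval
#' (internal 0-based half-open), an orientation, a copy state, and — for
#' dispersed segments — the location they are inserted at. Novel insertion
#' sequence is encoded with `chrom = "."` and `end - start` equal to the
#' inserted length.
#'
#' @param chrom,start,end source interval vectors.
#' @param orient `"+"` or `"-"` per segment.
#' @param copy integer copy state per segment: 0 (deleted), 1 (retained),
#'   >= 2 (duplicated).
#' @param ins_chrom,ins_pos insertion location for dispersed segments
#'   (NA for in-place segments).
#' @return data.frame of class `cpx_structure`.
#' @export
cpx_structure <- function(chrom, start, end, orient = "+", copy = 1L,
                          ins_chrom = NA_character_, ins_pos = NA_integer_) {
  df <- data.frame(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), orient = orient,
                   copy = as.integer(copy),
                   ins_chrom = ins_chrom, ins_pos = as.integer(ins_pos),
                   stringsAsFactors = FALSE)
  if (!nrow(df)) stop("a structure needs at least one segment")
  if (any(df$end < df$start)) stop("segment end < start")
  if (!all(df$orient %in% c("+", "-"))) stop("orientation must be + or -")
  real <- df[df$chrom != ".", ]
  if (nrow(real) > 1) {
    o <- order(real$chrom, real$start)
    s <- real[o, ]
    same <- s$chrom[-nrow(s)] == s$chrom[-1]
    if (any(same & s$end[-nrow(s)] > s$start[-1]))
      stop("overlapping source segments")
  }
  class(df) <- c("cpx_structure", "data.frame")
  df
}

# per-segment signature token
segment_token <- function(seg) {
  dispersed <- !is.na(seg$ins_pos)
  if (seg$chrom == ".") return("dINS")
  if (!dispersed) {
    if (seg$copy == 0L) return("DEL")
    if (seg$copy >= 2L) return("DUP")
    if (seg$orient == "-") return("INV")
    return("REF")
  }
  if (seg$copy >= 2L) return(if (seg$orient == "-") "dDUPINV" else "dDUP")
  "dSEG"
}

#' Canonical signature of an allele structure
#'
#' Orders in-place segments along the source (dispersed segments last) and
#' emits one token per segment, joined with `+` (e.g. `"DEL+INV"`,
#' `"dDUP"`). Mirror-image structures yield mirror signatures — the
#' distinction is retained; pair-collapsing is a reporting option of
#' [subclass_summary()]. Idempotent: reordering input segments does not
#' change the signature.
#'
#' @param structure a [cpx_structure()].
#' @return list with `structure` (canonically ordered) and `signature`
#'   (character scalar).
#' @export
canonicalize <- function(structure) {
  structure <- cpx_structure(structure$chrom, structure$start,
                             structure$end, structure$orient,
                             structure$copy, structure$ins_chrom,
                             structure$ins_pos)
  dispersed <- !is.na(structure$ins_pos)
  o <- order(dispersed, structure$chrom, structure$start)
  s <- structure[o, ]
  toks <- vapply(seq_len(nrow(s)), function(i) segment_token(s[i, ]),
                 character(1))
  keep <- toks != "REF"
  list(structure = s, signature = paste(toks[keep], collapse = "+"))
}

.flank_table <- c(
  "DEL+INV" = "delINV", "INV+DEL" = "INVdel",
  "DUP+INV" = "dupINV", "INV+DUP" = "INVdup",
  "DEL+INV+DEL" = "delINVdel", "DUP+INV+DUP" = "dupINVdup",
  "DEL+INV+DUP" = "delINVdup", "DUP+INV+DEL" = "dupINVdel")

.canonical_table <- c("DEL" = "DEL", "DUP" = "DUP", "INV" = "INV",
                      "dINS" = "INS")

#' Classify an allele structure into a complex-SV subclass
#'
#' Decision table over canonical signatures. Inversions with flanking
#' deletions/duplications map to the six INV-flank classes; a duplicated
#' segment inserted at a distant site maps to `dDUP` (with an insertion-site
#' deletion, `dDUP_iDEL`); novel insertion with an insertion-site deletion
#' maps to `INS_iDEL`. Single-signature structures route to their canonical
#' classes (`DEL`, `DUP`, `INV`, `INS`) and are flagged not complex.
#' Anything else is `unresolved`. Total: never errors on a valid structure.
#'
#' @param structure a [cpx_structure()].
#' @return list with `label`, `involves_inversion` (any `-` segment) and
#'   `is_complex`.
#' @export
classify_cpx <- function(structure) {
  can <- canonicalize(structure)
  s <- can$structure
  sig <- can$signature
  inv <- any(s$orient == "-")
  lab <- NULL
  if (sig %in% names(.canonical_table)) {
    # canonical single-signature alleles are not complex, except a novel
    # insertion deleting sequence at its insertion site (handled below)
    lab <- unname(.canonical_table[sig])
    return(list(label = lab, involves_inversion = inv, is_complex = FALSE))
  }
  if (sig %in% names(.flank_table))
    return(list(label = unname(.flank_table[sig]),
                involves_inversion = inv, is_complex = TRUE))

  disp <- which(!is.na(s$ins_pos))
  inplace <- which(is.na(s$ins_pos))
  if (length(disp) == 1 && length(inplace) <= 1) {
    d <- s[disp, ]
    tok <- segment_token(d)
    idel <- FALSE
    if (length(inplace) == 1) {
      ip <- s[inplace, ]
      idel <- segment_token(ip) == "DEL" && !is.na(d$ins_pos) &&
        ip$chrom == d$ins_chrom &&
        d$ins_pos >= ip$start - 1L && d$ins_pos <= ip$end + 1L
      if (!idel) return(list(label = "unresolved",
                             involves_inversion = inv, is_complex = TRUE))
    }
    if (tok %in% c("dDUP", "dDUPINV"))
      return(list(label = if (idel) "dDUP_iDEL" else "dDUP",
                  involves_inversion = inv, is_complex = TRUE))
    if (tok == "dINS" && idel)
      return(list(label = "INS_iDEL", involves_inversion = inv,
                  is_complex = TRUE))
  }
  list(label = "unresolved", involves_inversion = inv, is_complex = TRUE)
}

#' Summarize complex-SV subclass labels
#'
#' @param labels character vector of subclass labels.
#' @param involves_inversion logical vector aligned with `labels`; if NULL,
#'   inferred from the label (all INV-flank classes involve an inversion;
#'   `dDUP` may or may not, so supply the flag when available).
#' @param svlen,af optional aligned numeric vectors; medians per subclass
#'   are reported when given.
#' @param collapse_pairs collapse mirror pairs into single rows
#'   (`delINV/INVdel`, `dupINV/INVdup`, `delINVdup/dupINVdel`), the
#'   reporting view used for display.
#' @return list with `table` (per-subclass counts and medians) and
#'   `inversion_fraction`.
#' @export
subclass_summary <- function(labels, involves_inversion = NULL,
                             svlen = NULL, af = NULL,
                             collapse_pairs = FALSE) {
  if (!length(labels))
    return(list(table = data.frame(subclass = character(0),
                                   n = integer(0)),
                inversion_fraction = NA_real_))
  if (is.null(involves_inversion))
    involves_inversion <- grepl("INV|inv", labels)
  lab <- labels
  if (collapse_pairs) {
    pairs <- c(delINV = "delINV/INVdel", INVdel = "delINV/INVdel",
               dupINV = "dupINV/INVdup", INVdup = "dupINV/INVdup",
               delINVdup = "delINVdup/dupINVdel",
               dupINVdel = "delINVdup/dupINVdel")
    hit <- lab %in% names(pairs)
    lab[hit] <- pairs[lab[hit]]
  }
  tab <- as.data.frame(table(subclass = lab), stringsAsFactors = FALSE)
  names(tab)[2] <- "n"
  if (!is.null(svlen))
    tab$median_size <- as.numeric(tapply(svlen, lab, median,
                                         na.rm = TRUE)[tab$subclass])
  if (!is.null(af))
    tab$median_af <- as.numeric(tapply(af, lab, median,
                                       na.rm = TRUE)[tab$subclass])
  list(table = tab[order(-tab$n), ],
       inversion_fraction = mean(involves_inversion))
}

#' Generate an allele structure of a given subclass
#'
#' The simulator's inverse of [classify_cpx()]: builds a concrete segment
#' set whose classification is the requested label. Used by
#' [simulate_cohort()] and by the exhaustive round-trip tests.
#'
#' @param label one of the 11 subclass labels.
#' @param chrom,start placement. @param total_len approximate total span.
#' @return a [cpx_structure()].
#' @export
simulate_cpx_structure <- function(label, chrom = "chr1", start = 100000L,
                                   total_len = 3000L) {
  start <- as.integer(start)
  L <- max(as.integer(total_len), 300L)
  third <- L %/% 3L
  seg <- function(a, b, orient = "+", copy = 1L, ic = NA, ip = NA)
    data.frame(chrom = chrom, start = a, end = b, orient = orient,
               copy = copy, ins_chrom = ic, ins_pos = ip,
               stringsAsFactors = FALSE)
  b1 <- start + third; b2 <- start + 2L * third; b3 <- start + L
  df <- switch(label,
    delINV = rbind(seg(start, b1, copy = 0L), seg(b1, b3, "-")),
    INVdel = rbind(seg(start, b2, "-"), seg(b2, b3, copy = 0L)),
    dupINV = rbind(seg(start, b1, copy = 2L), seg(b1, b3, "-")),
    INVdup = rbind(seg(start, b2, "-"), seg(b2, b3, copy = 2L)),
    delINVdel = rbind(seg(start, b1, copy = 0L), seg(b1, b2, "-"),
                      seg(b2, b3, copy = 0L)),
    dupINVdup = rbind(seg(start, b1, copy = 2L), seg(b1, b2, "-"),
                      seg(b2, b3, copy = 2L)),
    delINVdup = rbind(seg(start, b1, copy = 0L), seg(b1, b2, "-"),
                      seg(b2, b3, copy = 2L)),
    dupINVdel = rbind(seg(start, b1, copy = 2L), seg(b1, b2, "-"),
                      seg(b2, b3, copy = 0L)),
    dDUP = seg(start, b2, sample(c("+", "-"), 1), copy = 2L,
               ic = chrom, ip = b3 + 5000L),
    dDUP_iDEL = rbind(
      seg(start, b2, sample(c("+", "-"), 1), copy = 2L,
          ic = chrom, ip = b3 + 5000L),
      seg(b3 + 5000L, b3 + 5000L + third, copy = 0L)),
    INS_iDEL = rbind(
      seg(start, start + third, ic = chrom, ip = b3 + 5000L, copy = 2L),
      seg(b3 + 5000L, b3 + 5000L + third, copy = 0L)),
    stop("unknown subclass label: ", label))
  if (label == "INS_iDEL") df$chrom[1] <- "."
  cpx_structure(df$chrom, df$start, df$end, df$orient, df$copy,
                df$ins_chrom, df$ins_pos)
}

#' Serialize / parse the CPX_INTERVALS token grammar
#'
#' Grammar (VCF dialect, 1-based inclusive): in-place segments
#' `DEL|DUP|INV_chrom:start-end`; dispersed duplications
#' `DDUP|DDUPINV_chrom:start-end@chrom:pos`; novel insertions
#' `INS_len@chrom:pos`. Tokens are comma-separated in source order.
#'
#' @param structure a [cpx_structure()].
#' @return `structure_to_string`: character scalar.
#' @export
structure_to_string <- function(structure) {
  s <- canonicalize(structure)$structure
  toks <- vapply(seq_len(nrow(s)), function(i) {
    seg <- s[i, ]
    if (seg$chrom == ".")
      return(sprintf("INS_%d@%s:%d", seg$end - seg$start, seg$ins_chrom,
                     seg$ins_pos + 1L))
    tok <- segment_token(seg)
    base <- sprintf("%s_%s:%d-%d", sub("^d", "D", tok), seg$chrom,
                    seg$start + 1L, seg$end)
    if (!is.na(seg$ins_pos))
      base <- sprintf("%s@%s:%d", base, seg$ins_chrom, seg$ins_pos + 1L)
    base
  }, character(1))
  paste(toks, collapse = ",")
}

#' @rdname structure_to_string
#' @param x token string (e.g. from the VCF `CPX_INTERVALS` INFO key).
#' @return `parse_cpx_intervals`: a [cpx_structure()].
#' @export
parse_cpx_intervals <- function(x) {
  toks <- strsplit(x, ",", fixed = TRUE)[[1]]
  rows <- lapply(toks, function(tk) {
    ins_chrom <- NA_character_; ins_pos <- NA_integer_
    if (grepl("@", tk, fixed = TRUE)) {
      at <- strsplit(tk, "@", fixed = TRUE)[[1]]
      tk <- at[1]
      loc <- strsplit(at[2], ":", fixed = TRUE)[[1]]
      ins_chrom <- loc[1]; ins_pos <- as.integer(loc[2]) - 1L
    }
    parts <- strsplit(tk, "_", fixed = TRUE)[[1]]
    op <- parts[1]
    if (op == "INS") {
      len <- as.integer(parts[2])
      return(data.frame(chrom = ".", start = 0L, end = len, orient = "+",
                        copy = 2L, ins_chrom = ins_chrom, ins_pos = ins_pos,
                        stringsAsFactors = FALSE))
    }
    loc <- strsplit(paste(parts[-1], collapse = "_"), "[:-]")[[1]]
    a <- as.integer(loc[2]) - 1L; b <- as.integer(loc[3])
    spec <- switch(op,
      DEL = list("+", 0L), DUP = list("+", 2L), INV = list("-", 1L),
      DDUP = list("+", 2L), DDUPINV = list("-", 2L),
      stop("unknown CPX token: ", op))
    data.frame(chrom = loc[1], start = a, end = b, orient = spec[[1]],
               copy = spec[[2]], ins_chrom = ins_chrom, ins_pos = ins_pos,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  cpx_structure(df$chrom, df$start, df$end, df$orient, df$copy,
                df$ins_chrom, df$ins_pos)
}
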