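#' Functional consequence of one SV against one gene model
#'
#' Decision table (all intervals 0-based half-open, coding = exonic):
#' \itemize{
#'   \item DEL overlapping >= 1 coding-exon bp: `pLoF`.
#'   \item INS with insertion point inside a coding exon: `pLoF`.
#'   \item INV / CTX / CPX with exactly one breakpoint inside the
#'     transcript span, or overlapping part but not all of the coding
#'     span: `pLoF`.
#'   \item DUP fully containing the transcript span: `copy_gain`.
#'   \item DUP with both breakpoints inside the span covering >= 1 entire
#'     coding exon: `IED` (intragenic exonic duplication); partial-exon
#'     duplication: `utr_partial`.
#'   \item INV fully containing the span: `whole_gene_inversion`.
#'   \item intron-only overlap: `intronic`; promoter-window hit without
#'     any other overlap: `promoter`; no overlap: `intergenic`.
#' }
#' CPX structures are classified per constituent segment (deleted segments
#' with DEL rules, duplicated with DUP rules, inverted with INV rules,
#' insertion points with INS rules) and the worst label is returned. MCNVs
#' follow DUP rules (dosage-altering CNVs).
#'
#' @param sv one-row data.frame (or list) with `svtype`, `chrom`, `start`,
#'   `end`, and optionally `cpx_structure`.
#' @param gene one-row data.frame with `chrom`, `start`, `end`, `strand`,
#'   `tss`.
#' @param exons data.frame of this gene's exons (`start`, `end`), sorted
#'   and non-overlapping (error otherwise).
#' @param promoter_bp promoter window upstream of the TSS, strand-aware
#'   (default 2000).
#' @return category string.
#' @export
classify_gene_overlap <- function(sv, gene, exons, promoter_bp = 2000) {
  if (sv$svtype == "BND") stop("BND records are excluded from annotation")
  if (is.unsorted(exons$start) || any(exons$end[-nrow(exons)] >
                                      exons$start[-1]) ||
      any(exons$start < gene$start) || any(exons$end > gene$end))
    stop("malformed gene model: exons must be sorted, non-overlapping ",
         "and inside the transcript span")
  .classify_one(sv$svtype, sv$chrom, sv$start, sv$end,
                if (!is.null(sv$cpx_structure)) sv$cpx_structure
                else NA_character_,
                gene, exons, promoter_bp)
}

.severity <- c(pLoF = 1, IED = 2, copy_gain = 3, whole_gene_inversion = 4,
               utr_partial = 5, promoter = 6, intronic = 7, intergenic = 8)

.worst <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) return("intergenic")
  names(which.min(.severity[labels]))
}

.classify_one <- function(svtype, chrom, start, end, cpx_struct, gene,
                          exons, promoter_bp) {
  if (chrom != gene$chrom && svtype != "CPX") return("intergenic")
  ov <- function(a, b) a < gene$end && b > gene$start
  exon_ov <- function(a, b) any(a < exons$end & b > exons$start)
  exon_full <- function(a, b) any(a <= exons$start & b >= exons$end)
  prom <- if (gene$strand == "+") c(gene$tss - promoter_bp, gene$tss)
          else c(gene$tss, gene$tss + promoter_bp)
  in_span <- function(p) p > gene$start && p < gene$end
  coding_lo <- min(exons$start); coding_hi <- max(exons$end)

  if (svtype == "INS") {
    if (!in_span(start) && !(start >= prom[1] && start < prom[2]))
      return("intergenic")
    if (start >= prom[1] && start < prom[2] && !in_span(start))
      return("promoter")
    if (exon_ov(start, start + 1L)) return("pLoF")
    return("intronic")
  }
  if (svtype == "CPX" && !is.na(cpx_struct)) {
    s <- parse_cpx_intervals(cpx_struct)
    labs <- vapply(seq_len(nrow(s)), function(i) {
      seg <- s[i, ]
      if (!is.na(seg$ins_pos)) {
        # the inserted material lands at ins_pos: INS rules there, and the
        # source segment (if duplicated from the reference) uses DUP rules
        at <- .classify_one("INS", seg$ins_chrom, seg$ins_pos,
                            seg$ins_pos, NA, gene, exons, promoter_bp)
        src <- if (seg$chrom == ".") "intergenic"
               else .classify_one("DUP", seg$chrom, seg$start, seg$end,
                                  NA, gene, exons, promoter_bp)
        return(.worst(c(at, src)))
      }
      type <- switch(segment_token(seg), DEL = "DEL", DUP = "DUP",
                     INV = "INV", "REF")
      if (type == "REF") return("intergenic")
      .classify_one(type, seg$chrom, seg$start, seg$end, NA, gene, exons,
                    promoter_bp)
    }, character(1))
    return(.worst(labs))
  }
  if (svtype == "CTX") {
    # a translocation is two breakpoints; disrupting iff one lands inside
    if (in_span(start) || in_span(end)) return("pLoF")
    if ((start >= prom[1] && start < prom[2]) ||
        (end >= prom[1] && end < prom[2])) return("promoter")
    return("intergenic")
  }
  if (svtype == "CPX") {   # unresolved structure: breakpoint rules
    one_in <- xor(in_span(start), in_span(end))
    part_of_coding <- ov(start, end) && exon_ov(start, end) &&
      !(start <= coding_lo && end >= coding_hi)
    if (in_span(start) && in_span(end))
      return(if (exon_ov(start, end)) "pLoF" else "intronic")
    if (one_in || part_of_coding) return("pLoF")
    if (start <= gene$start && end >= gene$end) return("pLoF")
    if (ov(start, end)) return("intronic")
    if (start < prom[2] && end > prom[1]) return("promoter")
    return("intergenic")
  }

  if (!ov(start, end)) {
    if (start < prom[2] && end > prom[1]) return("promoter")
    return("intergenic")
  }
  contains <- start <= gene$start && end >= gene$end
  both_in <- in_span(start) && in_span(end)
  if (svtype == "DEL")
    return(if (exon_ov(start, end)) "pLoF" else "intronic")
  if (svtype %in% c("DUP", "MCNV")) {
    if (contains) return("copy_gain")
    if (both_in && exon_full(start, end)) return("IED")
    return(if (exon_ov(start, end)) "utr_partial" else "intronic")
  }
  if (svtype == "INV") {
    if (contains) return("whole_gene_inversion")
    if (xor(in_span(start), in_span(end))) return("pLoF")
    # both breakpoints inside: disruptive iff part (not all) of the coding
    # span is rearranged
    if (exon_ov(start, end)) return("pLoF")
    return("intronic")
  }
  stop("unhandled SV type: ", svtype)
}

#' Coverage class of a CNV over a noncoding element
#'
#' `full` iff the element is entirely contained in the CNV interval;
#' `partial` for any other nonempty overlap; `none` otherwise.
#'
#' @param cnv one-row data.frame with `svtype`, `chrom`, `start`, `end`
#'   (must be DEL or DUP).
#' @param element one-row data.frame with `chrom`, `start`, `end`.
#' @return `"full"`, `"partial"` or `"none"`.
#' @export
classify_element_overlap <- function(cnv, element) {
  if (!cnv$svtype %in% c("DEL", "DUP"))
    stop("element overlap is defined for CNVs (DEL/DUP) only, got ",
         cnv$svtype)
  if (cnv$chrom != element$chrom) return("none")
  if (cnv$start <= element$start && cnv$end >= element$end) return("full")
  if (cnv$start < element$end && cnv$end > element$start) return("partial")
  "none"
}

#' Annotate a cohort against gene models and noncoding elements
#'
#' Applies [classify_gene_overlap()] to every (non-BND SV, candidate gene)
#' pair and [classify_element_overlap()] to every (CNV, element) pair,
#' using interval overlap (with the promoter window padded onto gene
#' spans) to restrict candidates. Deterministic and independent of input
#' record order.
#'
#' @param cohort an [sv_cohort()].
#' @param genes output of [simulate_gene_models()] or a list with `genes`
#'   and `exons` data.frames in the same layout.
#' @param elements optional elements data.frame (`element_id`, `chrom`,
#'   `start`, `end`, `class`).
#' @param promoter_bp promoter window (default 2000).
#' @return list with `gene_pairs` (`sv_id`, `gene_id`, `category`;
#'   intergenic pairs are not materialized), `element_pairs` (`sv_id`,
#'   `element_id`, `class`, `coverage`), `worst` (named character vector,
#'   one label per non-BND SV) and `category_counts`.
#' @export
annotate_cohort <- function(cohort, genes, elements = NULL,
                            promoter_bp = 2000) {
  g <- genes$genes
  if (anyDuplicated(g$gene_id)) stop("duplicate gene ids in gene models")
  ex_by_gene <- split(genes$exons[, c("start", "end")], genes$exons$gene_id)
  sites <- cohort$sites[cohort$sites$svtype != "BND", , drop = FALSE]

  pad <- promoter_bp
  q <- GenomicRanges::GRanges(sites$chrom,
         IRanges::IRanges(sites$start + 1L, pmax(sites$end, sites$start + 1L)))
  s <- GenomicRanges::GRanges(g$chrom,
         IRanges::IRanges(pmax(g$start - pad, 0) + 1L, g$end + pad))
  hits <- GenomicRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)

  cat <- character(length(qh))
  for (k in seq_along(qh)) {
    i <- qh[k]; j <- sh[k]
    cat[k] <- .classify_one(sites$svtype[i], sites$chrom[i], sites$start[i],
                            sites$end[i], sites$cpx_structure[i], g[j, ],
                            ex_by_gene[[g$gene_id[j]]], promoter_bp)
  }
  keep <- cat != "intergenic"
  gene_pairs <- data.frame(sv_id = sites$id[qh][keep],
                           gene_id = g$gene_id[sh][keep],
                           category = cat[keep], stringsAsFactors = FALSE)

  element_pairs <- NULL
  if (!is.null(elements) && nrow(elements)) {
    cnv <- sites[sites$svtype %in% c("DEL", "DUP"), , drop = FALSE]
    qe <- GenomicRanges::GRanges(cnv$chrom,
            IRanges::IRanges(cnv$start + 1L, pmax(cnv$end, cnv$start + 1L)))
    se <- GenomicRanges::GRanges(elements$chrom,
            IRanges::IRanges(elements$start + 1L, elements$end))
    eh <- GenomicRanges::findOverlaps(qe, se)
    i <- S4Vectors::queryHits(eh); j <- S4Vectors::subjectHits(eh)
    coverage <- ifelse(cnv$start[i] <= elements$start[j] &
                         cnv$end[i] >= elements$end[j], "full", "partial")
    element_pairs <- data.frame(sv_id = cnv$id[i],
                                element_id = elements$element_id[j],
                                class = elements$class[j],
                                coverage = coverage,
                                stringsAsFactors = FALSE)
  }

  worst <- setNames(rep("intergenic", nrow(sites)), sites$id)
  if (nrow(gene_pairs)) {
    w <- tapply(gene_pairs$category, gene_pairs$sv_id, .worst)
    worst[names(w)] <- as.character(w)
  }
  list(gene_pairs = gene_pairs, element_pairs = element_pairs,
       worst = worst,
       category_counts = table(factor(worst, levels = names(.severity))))
}
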