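#' Read a cohort SV callset from VCF
#'
#' Parses a VCF 4.2 file with symbolic alternate alleles (`<DEL>`, `<DUP>`,
#' `<CN0>`..`<CNk>`, `<INS>`, `<INV>`, `<CPX>`, `<CTX>`, `<BND>`) into an
#' [sv_cohort()]. VCF 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention (`start = POS - 1`, `end = END`).
#' INFO keys used: `SVTYPE` (required per record), `END`, `SVLEN`,
#' `CPX_TYPE`, `CPX_INTERVALS`. MCNV sites require a per-sample integer
#' `CN` FORMAT field.
#'
#' Allele counts are recomputed from genotypes of unrelated samples; when
#' the INFO fields `AC`/`AN` are present and disagree, a warning is issued
#' (the recomputed values win).
#'
#' @param path VCF file path (plain text).
#' @param sample_table optional sample table (data.frame or TSV path, see
#'   [read_sample_table()]); defaults to all samples unrelated, population
#'   `"OTH"`.
#' @return an [sv_cohort()].
#' @export
read_sv_vcf <- function(path, sample_table = NULL) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  pos_field <- vapply(strsplit(lines[body], "\t", fixed = TRUE),
                      function(f) f[2], character(1))
  bad <- which(!grepl("^[0-9]+$", pos_field))
  if (length(bad))
    stop("malformed coordinate at line ", body[bad[1]], " of ", path)

  v <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "cohort"))
  rr <- SummarizedExperiment::rowRanges(v)
  inf <- VariantAnnotation::info(v)
  n <- length(rr)

  svtype <- if ("SVTYPE" %in% names(inf)) as.character(inf$SVTYPE)
            else rep(NA_character_, n)
  keep <- !is.na(svtype)
  if (any(!keep))
    warning(sum(!keep), " record(s) rejected: missing SVTYPE (",
            paste(head(names(rr)[!keep]), collapse = ", "), ")")

  start <- GenomicRanges::start(rr) - 1L
  endi <- if ("END" %in% names(inf)) suppressWarnings(as.integer(inf$END))
          else rep(NA_integer_, n)
  svlen <- if ("SVLEN" %in% names(inf))
             suppressWarnings(abs(as.numeric(unlist_first(inf$SVLEN))))
           else rep(NA_real_, n)
  end <- ifelse(is.na(endi), start + ifelse(is.na(svlen), 0, svlen), endi)
  end[svtype %in% "INS"] <- start[svtype %in% "INS"]
  svlen <- ifelse(is.na(svlen), end - start, svlen)
  svlen[svtype %in% "BND"] <- NA_real_   # breakends have no resolved length

  cpx <- rep(NA_character_, n)
  if ("CPX_INTERVALS" %in% names(inf)) {
    raw <- inf$CPX_INTERVALS
    cpx <- vapply(seq_len(n), function(i) {
      x <- unlist(raw[i])
      if (!length(x) || all(is.na(x))) NA_character_
      else paste(x, collapse = ",")
    }, character(1))
  }

  flt <- as.character(rr$FILTER)
  flt[is.na(flt) | flt == "."] <- "PASS"

  sites <- data.frame(
    id = names(rr), chrom = as.character(GenomicRanges::seqnames(rr)),
    start = start, end = as.integer(end), svtype = svtype,
    svlen = as.numeric(svlen), filter = flt, cpx_structure = cpx,
    stringsAsFactors = FALSE)

  gtc <- VariantAnnotation::geno(v)$GT            # sites x samples
  gt <- t(gt_to_dosage(gtc))                      # samples x sites
  cn <- NULL
  if ("CN" %in% names(VariantAnnotation::geno(v))) {
    cnm <- t(VariantAnnotation::geno(v)$CN)
    mc <- sites$id[sites$svtype %in% "MCNV"]
    if (length(mc)) cn <- cnm[, mc, drop = FALSE]
  }
  gt[, sites$svtype %in% c("MCNV", "BND")] <- NA_integer_

  if (is.character(sample_table)) sample_table <- read_sample_table(sample_table)
  if (is.null(sample_table)) {
    sample_table <- data.frame(
      sample_id = rownames(gt), population = "OTH", sex = NA_character_,
      father_id = NA_character_, mother_id = NA_character_,
      is_unrelated = TRUE, stringsAsFactors = FALSE)
  } else {
    stopifnot(setequal(sample_table$sample_id, rownames(gt)))
    sample_table <- sample_table[match(rownames(gt), sample_table$sample_id), ]
  }

  sites <- sites[keep, , drop = FALSE]
  gt <- gt[, keep, drop = FALSE]
  cohort <- sv_cohort(sites, gt, sample_table, cn)

  for (key in c("AC", "AN")) {
    if (!key %in% names(inf)) next
    declared <- suppressWarnings(as.integer(unlist_first(inf[[key]])))[keep]
    got <- cohort$sites[[tolower(key)]]
    cmp <- !is.na(declared) & cohort$sites$svtype != "MCNV" & declared != got
    if (any(cmp))
      warning("INFO ", key, " disagrees with recomputed values for ",
              sum(cmp), " site(s), e.g. ", cohort$sites$id[which(cmp)[1]])
  }
  cohort
}

unlist_first <- function(x) {
  if (is.list(x) || methods::is(x, "List"))
    vapply(x, function(e) if (length(e)) as.numeric(e[1]) else NA_real_,
           numeric(1))
  else as.numeric(x)
}

# "0/1"-style strings -> alt-allele dosage (sites x samples in, same out)
gt_to_dosage <- function(gtc) {
  d <- matrix(NA_integer_, nrow(gtc), ncol(gtc),
              dimnames = dimnames(gtc))
  d[gtc %in% c("0/0", "0|0")] <- 0L
  d[gtc %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[gtc %in% c("1/1", "1|1")] <- 2L
  d
}

#' Write a cohort to the package's SV VCF dialect
#'
#' Inverse of [read_sv_vcf()]: internal 0-based half-open coordinates are
#' written as 1-based inclusive `POS`/`END`. Genotypes for all samples
#' (related included) are emitted as `GT`; MCNV copy numbers as `CN`.
#'
#' @param cohort an [sv_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(cohort, path) {
  sites <- cohort$sites
  chroms <- unique(sites$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svpopgen",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV class">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End coordinate (1-based inclusive)">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length in bp">',
    '##INFO=<ID=AC,Number=1,Type=Integer,Description="Alternate allele count (unrelated samples)">',
    '##INFO=<ID=AN,Number=1,Type=Integer,Description="Allele number (unrelated samples)">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Alternate allele frequency">',
    '##INFO=<ID=CPX_TYPE,Number=1,Type=String,Description="Complex SV subclass">',
    '##INFO=<ID=CPX_INTERVALS,Number=.,Type=String,Description="Ordered allele-structure tokens OP_chrom:start-end[@chrom:pos]">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=CN,Number=1,Type=Integer,Description="Diploid copy number (MCNV sites)">',
    paste0("##ALT=<ID=", c("DEL", "DUP", "INS", "INV", "CPX", "CTX", "BND"),
           ",Description=\"", c("Deletion", "Duplication", "Insertion",
                                "Inversion", "Complex SV", "Translocation",
                                "Breakend"), "\">"),
    vapply(chroms, function(ch) {
      sprintf("##contig=<ID=%s,length=%d>", ch,
              max(sites$end[sites$chrom == ch]) + 10000L)
    }, character(1)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$sample_id), collapse = "\t"))

  pos <- sites$start + 1L
  endv <- ifelse(sites$svtype == "INS", sites$start + 1L, sites$end)
  altv <- paste0("<", sites$svtype, ">")
  mc <- sites$svtype == "MCNV"
  if (any(mc) && !is.null(cohort$cn)) {
    altv[mc] <- vapply(sites$id[mc], function(id) {
      cns <- setdiff(sort(unique(cohort$cn[, id])), 2L)
      if (!length(cns)) cns <- 0L
      paste0("<CN", cns, ">", collapse = ",")
    }, character(1))
  }
  dotna <- function(x) ifelse(is.na(x), ".", as.character(x))
  info_str <- sprintf("SVTYPE=%s;END=%d;SVLEN=%s;AC=%s;AN=%s;AF=%s",
                      sites$svtype, endv,
                      dotna(as.integer(round(sites$svlen))),
                      dotna(sites$ac), dotna(sites$an),
                      dotna(signif(sites$af, 6)))
  has_cpx <- !is.na(sites$cpx_structure)
  info_str[has_cpx] <- paste0(info_str[has_cpx], ";CPX_INTERVALS=",
                              sites$cpx_structure[has_cpx])

  gt_str <- matrix("./.", nrow(cohort$samples), nrow(sites))
  if (!is.null(cohort$gt)) {
    gt_str[which(cohort$gt == 0L)] <- "0/0"
    gt_str[which(cohort$gt == 1L)] <- "0/1"
    gt_str[which(cohort$gt == 2L)] <- "1/1"
  }
  cn_str <- matrix(".", nrow(cohort$samples), nrow(sites))
  if (!is.null(cohort$cn)) {
    idx <- match(colnames(cohort$cn), sites$id)
    cn_str[, idx] <- ifelse(is.na(cohort$cn), ".",
                            as.character(cohort$cn))
  }
  fmt <- matrix(paste(gt_str, cn_str, sep = ":"),
                nrow(cohort$samples), nrow(sites))
  sample_block <- apply(fmt, 2, paste, collapse = "\t")

  rows <- paste(sites$chrom, pos, sites$id, "N", altv, ".", sites$filter,
                info_str, "GT:CN", sample_block, sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write per-site BED summary
#'
#' 0-based half-open BED with class, size, frequency and (optionally) the
#' worst functional consequence per site. One row per non-BND record;
#' zero-length insertion points are widened to 1 bp.
#'
#' @param cohort an [sv_cohort()].
#' @param path output path.
#' @param worst optional named character vector of per-SV worst-consequence
#'   labels (as returned by [annotate_cohort()]).
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(cohort, path, worst = NULL) {
  s <- cohort$sites[cohort$sites$svtype != "BND", , drop = FALSE]
  header <- "#chrom\tstart\tend\tid\tsvtype\tsvlen\taf\tconsequence"
  cons <- if (is.null(worst)) rep(".", nrow(s))
          else ifelse(is.na(worst[s$id]), ".", worst[s$id])
  rows <- paste(s$chrom, s$start, pmax(s$end, s$start + 1L), s$id, s$svtype,
                as.integer(round(s$svlen)),
                ifelse(is.na(s$af), ".", signif(s$af, 6)), cons, sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read/write the sample table
#'
#' TSV with columns `sample_id`, `population` (AFR/AMR/EAS/EUR/OTH),
#' `sex`, `father_id`, `mother_id`, `is_unrelated`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_table <- function(path) {
  st <- as.data.frame(data.table::fread(path, sep = "\t",
                                        na.strings = c("", "NA", ".")))
  stopifnot(all(c("sample_id", "population", "is_unrelated") %in% names(st)))
  st$is_unrelated <- as.logical(st$is_unrelated)
  for (col in c("sex", "father_id", "mother_id"))
    if (is.null(st[[col]])) st[[col]] <- NA_character_
  .check_trio_links(st)
  st
}

#' @rdname read_sample_table
#' @param samples sample table data.frame.
#' @export
write_sample_table <- function(samples, path) {
  data.table::fwrite(samples, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a chromosome-arm map
#'
#' Cytoband-like TSV with columns `chrom`, `arm` (`p`/`q`), `start`, `end`
#' (0-based half-open). The gap between the p-arm end and the q-arm start
#' of a chromosome is the centromere. A synthetic arm map ships with the
#' package (`system.file("extdata", "arm_map_synthetic.tsv",
#' package = "svpopgen")`); real cytoband files reduced to arms are read
#' the same way.
#'
#' @param path TSV path.
#' @return data.frame with one row per arm, sorted, plus `arm_len`.
#' @export
read_arm_map <- function(path) {
  am <- as.data.frame(data.table::fread(path, sep = "\t"))
  stopifnot(all(c("chrom", "arm", "start", "end") %in% names(am)))
  stopifnot(all(am$arm %in% c("p", "q")), all(am$end > am$start))
  am <- am[order(am$chrom, am$start), ]
  am$arm_len <- am$end - am$start
  am
}
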