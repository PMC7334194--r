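seg_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r$chrom %||% "chr1", start = r$start, end = r$end,
               orient = r$orient %||% "+", copy = r$copy %||% 1L,
               ins_chrom = r$ic %||% NA_character_,
               ins_pos = r$ip %||% NA_integer_)))
  cpx_structure(df$chrom, df$start, df$end, df$orient, df$copy,
                df$ins_chrom, df$ins_pos)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("canonical signatures order segments and keep mirror identity", {
  inv_only <- seg_df(list(start = 100, end = 500, orient = "-"))
  expect_equal(canonicalize(inv_only)$signature, "INV")
  expect_false(classify_cpx(inv_only)$is_complex)

  del_inv <- seg_df(list(start = 100, end = 300, copy = 0L),
                    list(start = 300, end = 600, orient = "-"))
  inv_del <- seg_df(list(start = 100, end = 400, orient = "-"),
                    list(start = 400, end = 600, copy = 0L))
  expect_equal(canonicalize(del_inv)$signature, "DEL+INV")
  expect_equal(canonicalize(inv_del)$signature, "INV+DEL")
  expect_equal(classify_cpx(del_inv)$label, "delINV")
  expect_equal(classify_cpx(inv_del)$label, "INVdel")

  # idempotence: segment order in the input is irrelevant
  shuffled <- del_inv[c(2, 1), ]
  expect_equal(canonicalize(shuffled)$signature, "DEL+INV")

  overlapping <- data.frame(chrom = "chr1", start = c(100, 200),
                            end = c(300, 400), orient = "+",
                            copy = c(0L, 0L))
  expect_error(cpx_structure(overlapping$chrom, overlapping$start,
                             overlapping$end, overlapping$orient,
                             overlapping$copy), "overlapping")
})

test_that("every catalogued subclass round-trips through its structure", {
  labels <- c("delINV", "INVdel", "dupINV", "INVdup", "delINVdel",
              "dupINVdup", "delINVdup", "dupINVdel", "dDUP", "dDUP_iDEL",
              "INS_iDEL")
  for (lab in labels) {
    for (rep in 1:5) {
      st <- withr::with_seed(rep * 100 + nchar(lab),
                             simulate_cpx_structure(lab,
                                                    total_len = 300 * rep))
      cls <- classify_cpx(st)
      expect_equal(cls$label, lab, label = lab)
      expect_equal(cls$involves_inversion, any(st$orient == "-"))
      # serialization round trip preserves the classification
      back <- parse_cpx_intervals(structure_to_string(st))
      expect_equal(classify_cpx(back)$label, lab,
                   label = paste(lab, "via string"))
    }
  }
})

test_that("exhaustive <= 3-token in-place structures never escape the label set", {
  known <- c(DEL = "DEL", DUP = "DUP", INV = "INV")
  toks <- names(known)
  combos <- c(
    lapply(toks, function(a) c(a)),
    do.call(c, lapply(toks, function(a) lapply(toks, function(b) c(a, b)))),
    do.call(c, do.call(c, lapply(toks, function(a)
      lapply(toks, function(b) lapply(toks, function(d) c(a, b, d)))))))
  valid <- c("DEL", "DUP", "INV", "delINV", "INVdel", "dupINV", "INVdup",
             "delINVdel", "dupINVdup", "delINVdup", "dupINVdel", "dDUP",
             "dDUP_iDEL", "INS_iDEL", "unresolved")
  expected_label <- function(tk) {
    sig <- paste(tk, collapse = "+")
    table <- c("DEL" = "DEL", "DUP" = "DUP", "INV" = "INV",
               "DEL+INV" = "delINV", "INV+DEL" = "INVdel",
               "DUP+INV" = "dupINV", "INV+DUP" = "INVdup",
               "DEL+INV+DEL" = "delINVdel", "DUP+INV+DUP" = "dupINVdup",
               "DEL+INV+DUP" = "delINVdup", "DUP+INV+DEL" = "dupINVdel")
    if (sig %in% names(table)) unname(table[sig]) else "unresolved"
  }
  for (tk in combos) {
    n <- length(tk)
    bounds <- seq(100, by = 200, length.out = n + 1)
    rows <- lapply(seq_len(n), function(i) {
      list(start = bounds[i], end = bounds[i + 1],
           orient = if (tk[i] == "INV") "-" else "+",
           copy = c(DEL = 0L, DUP = 2L, INV = 1L)[[tk[i]]])
    })
    st <- do.call(seg_df, rows)
    cls <- classify_cpx(st)
    expect_true(cls$label %in% valid)
    expect_equal(cls$label, expected_label(tk),
                 label = paste(tk, collapse = "+"))
  }
})

test_that("classification depends only on the canonical signature", {
  st <- simulate_cpx_structure("dupINVdel", total_len = 900)
  c1 <- classify_cpx(st)
  c2 <- classify_cpx(canonicalize(st)$structure)
  expect_identical(c1, c2)
})

test_that("subclass summaries count inversions the way the catalogue does", {
  s <- subclass_summary(c("delINV", "delINV", "dDUP"),
                        involves_inversion = c(TRUE, TRUE, FALSE))
  expect_equal(s$inversion_fraction, 2 / 3)
  expect_equal(s$table$n[s$table$subclass == "delINV"], 2)

  # headline arithmetic: 3,901 of 5,295 complex SVs involve inversions
  labs <- rep(c("dupINV", "dDUP"), c(3901, 5295 - 3901))
  inv <- rep(c(TRUE, FALSE), c(3901, 5295 - 3901))
  expect_equal(round(100 * subclass_summary(labs, inv)$inversion_fraction,
                     1), 73.7)

  empty <- subclass_summary(character(0))
  expect_equal(nrow(empty$table), 0)

  coll <- subclass_summary(c("delINV", "INVdel", "dDUP"),
                           collapse_pairs = TRUE)
  expect_true("delINV/INVdel" %in% coll$table$subclass)
  expect_equal(coll$table$n[coll$table$subclass == "delINV/INVdel"], 2)
})
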