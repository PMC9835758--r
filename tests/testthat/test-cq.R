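fake_track <- function(rpkm, width = 10000L, scaffold = "s") {
  n <- length(rpkm)
  widths <- rep_len(width, n)
  ends <- cumsum(widths)
  out <- tibble::tibble(
    scaffold = scaffold, start = c(0L, head(ends, -1)),
    end = ends, index = seq_len(n), width = widths,
    partial = widths < max(widths), count = NA_integer_, rpkm = rpkm
  )
  attr(out, "window_size") <- max(widths)
  out
}

test_that("region CQ implements the zero-denominator semantics", {
  f <- fake_track(c(4, 0, 1, 0))
  m <- fake_track(c(2, 0, 0, 5))
  cq <- region_cq(f, m)
  expect_equal(cq$cq, c(2, NA, Inf, 0))
  expect_error(region_cq(f, fake_track(c(1, 1, 1))), "tiling")
})

test_that("window tags honour the strict CQ thresholds", {
  cq <- region_cq(fake_track(c(0.03, 2, 1, 3, 1, 0)),
                  fake_track(c(1, 1, 1, 1, 0, 0)))
  tags <- tag_regions(cq)
  # 0.03 is a Y signature; exactly 2 is neutral ("above 2" is strict);
  # +Inf counts as X; 0/0 stays undefined
  expect_identical(tags$tag, c("Y", "neutral", "neutral", "X", "X",
                               "undefined"))
  # short windows are left undefined regardless of CQ
  short <- region_cq(fake_track(c(1, 0.01), width = c(10000L, 3000L)),
                     fake_track(c(1, 1), width = c(10000L, 3000L)))
  attr(short, "window_size") <- 10000L
  expect_identical(tag_regions(short)$tag, c("neutral", "undefined"))
})

test_that("re-deriving tags from stored CQ reproduces them; Y tags grow with y_max", {
  set.seed(5)
  vals <- c(runif(200, 0, 4), Inf, Inf, NA, 0)
  cq <- region_cq(fake_track(ifelse(is.na(vals), 0, pmin(vals, 1e6))),
                  fake_track(ifelse(is.na(vals) | is.infinite(vals), 0, 1)))
  t1 <- tag_regions(cq)
  t2 <- tag_regions(dplyr::select(t1, -"tag"))
  expect_identical(t1$tag, t2$tag)
  loose <- tag_regions(cq, cq_thresholds(y_max = 0.5))
  expect_true(all(which(t1$tag == "Y") %in% which(loose$tag == "Y")))
})

test_that("scaffold calls follow the 40%-of-length rule", {
  # 346 of 455 windows above CQ 2 -> 76% of length, a clear X call
  x315 <- tag_regions(region_cq(fake_track(c(rep(3, 346), rep(1, 109))),
                                fake_track(rep(1, 455))))
  call <- call_scaffolds(x315)
  expect_equal(call$fraction_x, 346 / 455, tolerance = 1e-12)
  expect_identical(call$call, "X-candidate")

  neutral <- tag_regions(region_cq(fake_track(rep(1, 10)),
                                   fake_track(rep(1, 10))))
  call0 <- call_scaffolds(neutral)
  expect_identical(call0$call, "unassigned")
  expect_equal(call0$fraction_x + call0$fraction_y, 0)

  # average CQ excludes infinite windows and reports the exclusion
  mixed <- tag_regions(region_cq(fake_track(c(1, 2, 3)),
                                 fake_track(c(1, 1, 0))))
  cm <- call_scaffolds(mixed)
  expect_equal(cm$average_cq, 1.5)
  expect_identical(cm$n_cq_infinite, 1L)
})

test_that("a simulated Y scaffold is called Y-candidate", {
  sim <- simulate_assembly(tiny_config(mean_depth = 20))
  pf <- place_reads(simulate_reads(sim, "female"), sim$assembly)
  pm <- place_reads(simulate_reads(sim, "male"), sim$assembly)
  w <- tile_windows(sim$assembly)
  tags <- tag_regions(region_cq(window_rpkm(pf, w), window_rpkm(pm, w)))
  calls <- call_scaffolds(tags)
  expect_identical(calls$call[calls$scaffold == "y_1"], "Y-candidate")
  expect_identical(calls$call[calls$scaffold == "autosome_1"], "unassigned")
})

test_that("gene CQ normalizes by library size with region semantics", {
  gc_tbl <- function(f, m, fl, ml) {
    fc <- tibble::tibble(gene_id = "g", scaffold = "s", start = 0L,
                         end = 100L, count = f, library_size = fl)
    mc <- tibble::tibble(gene_id = "g", scaffold = "s", start = 0L,
                         end = 100L, count = m, library_size = ml)
    gene_cq(fc, mc)$gene_cq
  }
  expect_equal(gc_tbl(10, 10, 1e6, 1e6), 1)
  expect_equal(gc_tbl(5, 100, 1e6, 1e6), 0.05)
  expect_equal(gc_tbl(10, 10, 2e6, 1e6), 0.5)
  expect_equal(gc_tbl(0, 0, 1e6, 1e6), NA_real_)
  expect_equal(gc_tbl(3, 0, 1e6, 1e6), Inf)
  expect_error(gc_tbl(1, 1, 0, 1e6), "library")
  # scale invariance: scaling both libraries and counts leaves CQ fixed
  expect_equal(gc_tbl(40, 10, 4e6, 1e6), gc_tbl(80, 20, 8e6, 2e6))
})

test_that("context CQ uses the midpoint window, with a weighted report", {
  tags <- tag_regions(region_cq(fake_track(c(0.1, 0.3) * 10),
                                fake_track(c(10, 10))))
  # wholly inside window 1
  g1 <- tibble::tibble(gene_id = "g1", scaffold = "s", start = 2000L,
                       end = 4000L)
  expect_equal(context_cq(g1, tags)$context_cq, 0.1)
  # midpoint exactly on the boundary goes to the later window
  g2 <- tibble::tibble(gene_id = "g2", scaffold = "s", start = 9000L,
                       end = 11000L)
  expect_equal(context_cq(g2, tags)$context_cq, 0.3)
  # spanning gene: midpoint window plus length-weighted mean
  g3 <- tibble::tibble(gene_id = "g3", scaffold = "s", start = 8000L,
                       end = 12000L)
  ctx <- context_cq(g3, tags)
  expect_equal(ctx$context_cq, 0.3)  # midpoint 10000 -> window 2
  expect_equal(ctx$context_cq_weighted, (0.1 * 2000 + 0.3 * 2000) / 4000)
  g4 <- tibble::tibble(gene_id = "g4", scaffold = "s", start = 6000L,
                       end = 10000L)
  expect_equal(context_cq(g4, tags)$context_cq, 0.1)
  expect_equal(context_cq(g4, tags)$context_cq_weighted, 0.1)
})

test_that("gene assignment requires both gene and context CQ to pass", {
  gene_cqs <- tibble::tibble(
    gene_id = c("g17083", "g10424", "gMixed", "gX"),
    gene_cq = c(0.1, 0.0, 3.0, 2.8)
  )
  ctx <- tibble::tibble(
    gene_id = gene_cqs$gene_id,
    context_cq = c(0.05, 0.1, 1.0, 2.5)
  )
  a <- assign_genes(gene_cqs, ctx)
  expect_identical(a$assignment, c("Y", "Y", "none", "X"))
})
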