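edge_df <- function(...) {
  m <- rbind(...)
  data.frame(protein_a = m[, 1], protein_b = m[, 2],
             weight = as.numeric(m[, 3]), stringsAsFactors = FALSE)
}

test_that("min-max adjacency normalization maps weights onto [0, 1]", {
  net <- ppi_network(edge_df(c("a", "b", 1000), c("b", "c", 500)))
  A <- normalize_adjacency(net)
  expect_equal(A["a", "b"], 1.0)
  expect_equal(A["b", "c"], 0.5)
  expect_equal(A["a", "c"], 0.0)
  expect_identical(A, t(A))
  # two proteins, one edge
  A2 <- normalize_adjacency(ppi_network(edge_df(c("a", "b", 700))))
  expect_equal(A2, matrix(c(0, 1, 1, 0), 2,
                          dimnames = list(c("a", "b"), c("a", "b"))))
  # error paths
  expect_error(ppi_network(edge_df(c("a", "b", -5))), "negative")
  expect_error(normalize_adjacency(
    ppi_network(edge_df(c("a", "b", 0)), proteins = c("a", "b"))),
    "degenerate")
})

test_that("normalization preserves rank order and is idempotent", {
  set.seed(3)
  prot <- sprintf("p%02d", 1:50)
  pairs <- t(combn(prot, 2))
  keep <- runif(nrow(pairs)) < 0.15
  e <- data.frame(protein_a = pairs[keep, 1], protein_b = pairs[keep, 2],
                  weight = sample(100:999, sum(keep), replace = TRUE))
  net <- ppi_network(e, proteins = prot)
  A <- normalize_adjacency(net)
  expect_equal(min(A), 0)
  expect_equal(max(A), 1)
  # rank order of entries preserved against the raw weight matrix
  raw <- matrix(0, 50, 50, dimnames = list(prot, prot))
  raw[cbind(e$protein_a, e$protein_b)] <- e$weight
  raw[cbind(e$protein_b, e$protein_a)] <- e$weight
  expect_true(all(diff(raw[order(A)]) >= 0))
  # idempotence: re-normalizing the normalized network changes nothing
  ut <- upper.tri(A)
  e2 <- data.frame(protein_a = rownames(A)[row(A)[ut]],
                   protein_b = colnames(A)[col(A)[ut]],
                   weight = A[ut])
  e2 <- e2[e2$weight > 0, ]
  expect_equal(normalize_adjacency(ppi_network(e2, proteins = prot)), A)
})

test_that("attribute matrix applies the domain-frequency filter", {
  prot <- sprintf("p%d", 1:10)
  dom <- data.frame(protein = c(prot[1:6], prot[1:5]),
                    term = rep(c("D1", "D2"), c(6, 5)))
  loc <- data.frame(protein = prot[1:2], term = "L1")
  M <- build_attribute_matrix(dom, loc, prot)
  expect_equal(colnames(M), c("D1", "L1"))
  expect_equal(ncol(M), 2)
  expect_equal(unname(M["p1", ]), c(1, 1))
  expect_equal(unname(M["p9", ]), c(0, 0))
  expect_equal(attr(M, "n_domain"), 1L)
  expect_error(build_attribute_matrix(dom[0, ], loc[0, ], prot),
               "min_domain_count")
})

test_that("retained domain columns always meet the frequency threshold", {
  set.seed(5)
  prot <- sprintf("p%03d", 1:100)
  dom <- data.frame(protein = sample(prot, 400, replace = TRUE),
                    term = sample(sprintf("D%02d", 1:25), 400, replace = TRUE))
  loc <- data.frame(protein = sample(prot, 80, replace = TRUE),
                    term = sample(sprintf("L%02d", 1:5), 80, replace = TRUE))
  M <- build_attribute_matrix(dom, loc, prot)
  nd <- attr(M, "n_domain")
  expect_true(all(colSums(M[, seq_len(nd)]) >= 6))
  # recount from the raw annotations
  cnt <- table(unique(dom)$term)
  expect_setequal(colnames(M)[seq_len(nd)], names(cnt)[cnt >= 6])
})

test_that("evidence filtering keeps exactly the allowed codes in order", {
  tab <- annotation_table(data.frame(
    protein = letters[1:5], go_term = "GO:0000001", aspect = "BPO",
    evidence = c("IDA", "IEA", "EXP", "ISS", "IMP"),
    date = "2019-01-01"))
  kept <- filter_evidence(tab)
  expect_equal(kept$evidence, c("IDA", "EXP", "IMP"))
  expect_equal(kept$protein, c("a", "c", "e"))
  expect_equal(nrow(filter_evidence(tab[0, ])), 0)
  # survivor count equals an independent recount on random codes
  set.seed(1)
  codes <- c(EXPERIMENTAL_EVIDENCE, "IEA", "ISS", "NAS", "ND")
  big <- annotation_table(data.frame(
    protein = sample(letters, 1000, TRUE), go_term = "GO:0000002",
    aspect = "MFO", evidence = sample(codes, 1000, TRUE),
    date = "2020-06-06"))
  expect_equal(nrow(filter_evidence(big)),
               sum(big$evidence %in% EXPERIMENTAL_EVIDENCE))
})

test_that("temporal split routes proteins by their annotation dates", {
  tab <- annotation_table(data.frame(
    protein = c("tr", "tr", "va", "te"),
    go_term = "GO:0000001", aspect = "BPO", evidence = "IDA",
    date = c("2017-05-01", "2019-02-02", "2019-02-02", "2021-03-03")))
  a <- temporal_split(tab)
  expect_equal(a[["tr"]], "train")
  expect_equal(a[["va"]], "val")
  expect_equal(a[["te"]], "test")
  # boundary dates: exactly t0 -> train, exactly t1 -> val
  tb <- annotation_table(data.frame(
    protein = c("x", "y"), go_term = "GO:0000001", aspect = "BPO",
    evidence = "IDA", date = c("2018-01-01", "2020-12-31")))
  ab <- temporal_split(tb)
  expect_equal(unname(ab[c("x", "y")]), c("train", "val"))
  expect_error(temporal_split(tab, t0 = "2020-01-01", t1 = "2019-01-01"),
               "precede")
})

test_that("temporal split partitions the annotated proteins", {
  set.seed(2)
  tab <- annotation_table(data.frame(
    protein = sample(sprintf("p%03d", 1:300), 900, replace = TRUE),
    go_term = "GO:0000001", aspect = "BPO", evidence = "IDA",
    date = as.character(as.Date("2015-01-01") +
                          sample.int(2900, 900, replace = TRUE))))
  a <- temporal_split(tab)
  expect_setequal(names(a), unique(tab$protein))
  expect_true(all(a %in% c("train", "val", "test")))
  # assignment agrees with a set-algebra recheck per protein
  for (p in sample(names(a), 30)) {
    d <- tab$date[tab$protein == p]
    want <- if (any(d <= as.Date("2018-01-01"))) "train"
    else if (any(d <= as.Date("2020-12-31"))) "val" else "test"
    expect_equal(unname(a[p]), want)
  }
})

test_that("GO-term selection enforces both threshold families exactly", {
  tab <- make_term_table(list(
    "GO:0000010" = c(10, 5, 1),   # at every minimum -> kept
    "GO:0000020" = c(9, 5, 1),    # one short on train -> dropped
    "GO:0000030" = c(30, 20, 12)  # 62 proteins: > 5% of N = 1000 -> dropped
  ))
  prot <- unique(tab$protein)
  filler <- sprintf("iso%04d", seq_len(1000 - length(prot)))
  net <- ppi_network(
    data.frame(protein_a = "iso0001", protein_b = "iso0002", weight = 500),
    proteins = c(prot, filler))
  a <- temporal_split(tab)
  sp <- select_go_terms(a, tab, net)
  expect_equal(sp$go_terms, "GO:0000010")
  expect_equal(sum(sp$Y_train), 10)
  expect_equal(sum(sp$Y_val), 5)
  expect_equal(sum(sp$Y_test), 1)
})

test_that("the network-fraction cap is strict (exactly 5% is kept)", {
  # N = 100; a term annotating exactly 5 proteins survives ("more than 5%")
  tab <- make_term_table(list("GO:0000099" = c(10, 5, 1)))
  # 16 annotated proteins > 5% of 100, so widen: craft a 5-protein term
  tab5 <- annotation_table(data.frame(
    protein = sprintf("q%d", 1:5), go_term = "GO:0000050", aspect = "BPO",
    evidence = "IDA",
    date = c("2016-01-01", "2016-01-01", "2016-01-01", "2019-06-01",
             "2021-06-01")))
  prot <- c(unique(tab5$protein), sprintf("iso%03d", 1:95))
  net <- ppi_network(
    data.frame(protein_a = "iso001", protein_b = "iso002", weight = 1),
    proteins = prot)
  a <- temporal_split(tab5)
  sp <- select_go_terms(a, tab5, net, min_train = 3, min_val = 1,
                        min_test = 1)
  expect_equal(sp$go_terms, "GO:0000050")
  # one protein more (6 of 100) exceeds the cap and kills the term
  tab6 <- annotation_table(rbind(as.data.frame(tab5), data.frame(
    protein = "q6", go_term = "GO:0000050", aspect = "BPO",
    evidence = "IDA", date = "2016-02-01")))
  a6 <- temporal_split(tab6)
  expect_error(select_go_terms(a6, tab6, ppi_network(
    data.frame(protein_a = "iso001", protein_b = "iso002", weight = 1),
    proteins = c(unique(tab6$protein), sprintf("iso%03d", 1:94))),
    min_train = 3, min_val = 1, min_test = 1),
    "max_network_fraction")
})

test_that("surviving term count equals a brute-force recount", {
  set.seed(4)
  n_prot <- 150
  prot <- sprintf("p%03d", seq_len(n_prot))
  tab <- annotation_table(data.frame(
    protein = sample(prot, 1200, replace = TRUE),
    go_term = sample(sprintf("GO:%07d", 1:12), 1200, replace = TRUE),
    aspect = "BPO", evidence = "IDA",
    date = as.character(as.Date("2015-01-01") +
                          sample.int(2900, 1200, replace = TRUE))))
  net <- ppi_network(
    data.frame(protein_a = prot[1], protein_b = prot[2], weight = 1),
    proteins = prot)
  a <- temporal_split(tab)
  sp <- tryCatch(select_go_terms(a, tab, net, min_train = 5, min_val = 2,
                                 min_test = 1, max_network_fraction = 0.6),
                 error = function(e) NULL)
  # independent recount
  pairs <- unique(tab[, c("protein", "go_term")])
  pairs$set <- a[pairs$protein]
  keep <- vapply(unique(pairs$go_term), function(tm) {
    s <- pairs[pairs$go_term == tm, ]
    sum(s$set == "train") >= 5 && sum(s$set == "val") >= 2 &&
      sum(s$set == "test") >= 1 && nrow(s) <= 0.6 * n_prot
  }, logical(1))
  expect_equal(length(sp$go_terms), sum(keep))
  expect_setequal(sp$go_terms, names(keep)[keep])
  # every kept column satisfies the thresholds
  expect_true(all(colSums(sp$Y_train) >= 5))
  expect_true(all(colSums(sp$Y_val) >= 2))
  expect_true(all(colSums(sp$Y_test) >= 1))
})

test_that("merging train and validation concatenates their rows", {
  # counts mirroring the human BPO statistics: 3197 + 304 = 3501
  K <- 2
  mk <- function(n, pre) matrix(1L, n, K,
                                dimnames = list(sprintf("%s%04d", pre,
                                                        seq_len(n)),
                                                c("GO:1", "GO:2")))
  sp <- structure(list(aspect = "BPO", go_terms = c("GO:1", "GO:2"),
                       train_proteins = sprintf("t%04d", 1:3197),
                       val_proteins = sprintf("v%04d", 1:304),
                       test_proteins = sprintf("s%04d", 1:182),
                       Y_train = mk(3197, "t"), Y_val = mk(304, "v"),
                       Y_test = mk(182, "s")),
                  class = "dataset_split")
  m <- merge_train_val(sp)
  expect_equal(nrow(m$Y_train), 3501)
  expect_length(m$train_proteins, 3501)
  expect_length(m$val_proteins, 0)
  expect_identical(m$Y_test, sp$Y_test)
  expect_identical(m$go_terms, sp$go_terms)
  # empty validation set leaves training unchanged
  sp0 <- sp
  sp0$Y_val <- sp$Y_val[0, , drop = FALSE]
  sp0$val_proteins <- character(0)
  expect_identical(merge_train_val(sp0)$Y_train, sp$Y_train)
})

test_that("splits round-trip through their on-disk text form", {
  ds <- synth_generate(synth_spec(seed = 6))
  prep <- desk_preprocess(ds)
  dir <- withr::local_tempdir()
  write_split(prep$split, dir)
  back <- read_split(dir)
  expect_identical(back$go_terms, prep$split$go_terms)
  expect_identical(back$Y_train, prep$split$Y_train)
  expect_identical(back$Y_val, prep$split$Y_val)
  expect_identical(back$Y_test, prep$split$Y_test)
  # merged split keeps row count additivity
  m <- merge_train_val(prep$split)
  expect_equal(nrow(m$Y_train),
               nrow(prep$split$Y_train) + nrow(prep$split$Y_val))
})

test_that("network files round-trip through the STRING-style reader", {
  ds <- synth_generate(synth_spec(seed = 8))
  dir <- withr::local_tempdir()
  paths <- synth_write_fixture(ds, dir)
  net <- read_ppi_network(paths[["network"]])
  A1 <- normalize_adjacency(net)
  A2 <- normalize_adjacency(ds$network)
  expect_equal(A1[rownames(A2), colnames(A2)], A2)
})
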