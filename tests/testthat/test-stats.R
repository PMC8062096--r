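# Significance mathematics: length adjustment, e-value formulas, correction
# laws and the reporting arithmetic.

test_that("length adjustment handles degenerate and slope-zero cases", {
  p0 <- karlin_params(lambda = 1, K = 0.5, alpha = 0, beta = 7)
  expect_identical(length_adjustment(p0, m = 100, n = 1e5, N = 10), 7L)
  # single-residue query: clamped to l = 0 so m_eff stays >= 1
  expect_identical(length_adjustment(blastn_params(), m = 1, n = 1e5, N = 10), 0L)
  expect_error(length_adjustment(blastn_params(), m = 0, n = 1e5, N = 10),
               class = "incblast_domain_error")
  expect_error(length_adjustment(blastn_params(), m = 100, n = 0, N = 10),
               class = "incblast_domain_error")
  expect_error(length_adjustment(blastn_params(), m = 100, n = 1e5, N = 0),
               class = "incblast_domain_error")
})

test_that("iterative solver matches the exhaustive-scan oracle", {
  p <- karlin_params(lambda = 0.625, K = 0.41, H = 0.78, alpha = 0.8, beta = -2)
  expect_identical(length_adjustment(p, m = 1000, n = 1e6, N = 100),
                   oracle_length_adjustment(p, m = 1000, n = 1e6, N = 100))
  set.seed(101)
  for (i in 1:200) {
    m <- sample(2:1000, 1)
    N <- sample(1:1000, 1)
    n <- N * sample(20:10000, 1)
    pp <- karlin_params(lambda = runif(1, 0.2, 1.4), K = runif(1, 0.05, 0.7),
                        H = runif(1, 0.1, 1.2), alpha = runif(1, 0, 2.5),
                        beta = runif(1, -5, 2))
    expect_identical(length_adjustment(pp, m, n, N),
                     oracle_length_adjustment(pp, m, n, N))
  }
})

test_that("search space fields stay consistent", {
  sp <- effective_search_space(blastn_params(), m = 1000, n = 1e6, N = 100)
  expect_identical(sp$D, sp$m_eff * sp$n_eff)
  expect_gt(sp$m_eff, 0)
  expect_gt(sp$n_eff, 0)
  expect_error(search_space(10, 1e4, 100, 100), class = "incblast_domain_error")
})

test_that("e-values from scores follow E = K m' n' exp(-lambda S)", {
  p <- karlin_params(lambda = 0.625, K = 0.41, H = 0.78, alpha = 0.8, beta = -2)
  sp <- list(m_eff = 950, n_eff = 9e5)
  # zero score: the exponential term is 1
  expect_equal(evalue_from_score(p, sp, 0)$log_e, log(0.41 * 950 * 9e5))
  # linear in n': doubling the database adds exactly ln 2
  sp2 <- list(m_eff = 950, n_eff = 1.8e6)
  expect_equal(evalue_from_score(p, sp2, 60)$log_e,
               evalue_from_score(p, sp, 60)$log_e + log(2))
  # frozen extended-precision evaluation of ln(K m' n') - lambda S
  expect_equal(evalue_from_score(p, sp, 60)$log_e, -17.8249860923827492,
               tolerance = 1e-14)
  # extreme scores never collapse to zero
  tiny <- evalue_from_score(p, sp, 5000)
  expect_true(is.finite(tiny$log_e))
  expect_false(format_evalue(tiny) == "0")
})

test_that("additive correction agrees with recomputation on the union space", {
  p <- blastn_params()
  expect_equal(correct_evalue_ka(p, blast_evalue(-30), 50, 1e8, 1e8)$log_e, -30)
  e1 <- evalue_from_score(p, list(m_eff = 500, n_eff = 2e5), 40)
  e2 <- correct_evalue_ka(p, e1, 40, 1e8, 2e8)
  expect_equal(evalue_linear(e2), 2 * evalue_linear(e1), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:100) {
    sc <- sample(20:300, 1)
    m_eff <- sample(50:2000, 1)
    n1 <- sample(1e4:1e6, 1)
    grow <- runif(1, 1, 50)
    ep <- evalue_from_score(p, list(m_eff = m_eff, n_eff = n1), sc)
    et <- correct_evalue_ka(p, ep, sc, m_eff * n1, m_eff * n1 * grow)
    direct <- evalue_from_score(p, list(m_eff = m_eff, n_eff = n1 * grow), sc)
    expect_equal(et$log_e, direct$log_e, tolerance = 1e-10)
    expect_gte(et$log_e, ep$log_e)  # e-values never improve as the db grows
  }
  expect_error(correct_evalue_ka(p, blast_evalue(-10), 30, 1e8, 1e7),
               class = "incblast_domain_error")
  expect_error(correct_evalue_ka(p, blast_evalue(-Inf, TRUE), 30, 1e8, 2e8),
               class = "incblast_zero_rounded_error")
})

test_that("Spouge rescaling is exact in log space", {
  e <- blast_evalue(-50)
  expect_equal(rescale_evalue_spouge(e, 1e6, 1e6)$log_e, -50)
  expect_equal(rescale_evalue_spouge(e, 1e6, 3e6)$log_e, -50 + log(3))
  set.seed(11)
  for (i in 1:200) {
    ns <- sort(10^runif(3, 3, 11))
    le <- runif(1, -400, 2)
    ab <- rescale_evalue_spouge(blast_evalue(le), ns[1], ns[2])
    abc <- rescale_evalue_spouge(ab, ns[2], ns[3])
    ac <- rescale_evalue_spouge(blast_evalue(le), ns[1], ns[3])
    expect_equal(abc$log_e, ac$log_e, tolerance = 1e-12)
    expect_gte(abc$log_e, le)  # monotone under growth
  }
  expect_error(rescale_evalue_spouge(blast_evalue(-Inf, TRUE), 1e6, 2e6),
               class = "incblast_zero_rounded_error")
})

test_that("growth and speedup arithmetic matches the reporting conventions", {
  expect_equal(growth_fraction(44.5, 62.7), 40.8)
  expect_equal(growth_fraction(62.7, 84.1), 34.1)
  expect_equal(growth_fraction(35.4, 47.5), 34.1)
  expect_equal(growth_fraction(50, 50), 0)
  expect_equal(growth_fraction(50, 75), 50)
  expect_error(growth_fraction(0, 10), class = "incblast_domain_error")
  expect_equal(round(projected_speedup(0.48), 2), 3.08)
  expect_equal(projected_speedup(1), 2)
  expect_equal(projected_speedup(0.10), 11)
  expect_error(projected_speedup(0), class = "incblast_domain_error")
})

test_that("programs route to their statistics family", {
  expect_identical(stats_family("blastn"), "karlin-altschul")
  expect_identical(stats_family("megablast"), "karlin-altschul")
  expect_identical(stats_family("tblastx"), "karlin-altschul")
  expect_identical(stats_family("blastp"), "spouge")
  expect_identical(stats_family("blastx"), "spouge")
  expect_identical(stats_family("tblastn"), "spouge")
  expect_error(stats_family("hmmer"), class = "incblast_domain_error")
})

test_that("parameter lookup finds tabulated schemes and falls back sensibly", {
  p <- lookup_karlin_params("blastn", reward = 1, penalty = -2,
                            gap_open = 0, gap_extend = 0)
  expect_equal(c(p$lambda, p$K, p$alpha, p$beta), c(1.28, 0.46, 1.5, -2))
  p62 <- lookup_karlin_params("blastp", matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1)
  expect_equal(c(p62$alpha, p62$beta), c(1.9, -30))
  # statistics-block values take precedence over tabulated lambda/K/H
  p2 <- lookup_karlin_params("blastn", reward = 1, penalty = -2,
                             gap_open = 0, gap_extend = 0,
                             stats_lambda = 1.3, stats_K = 0.5, stats_H = 0.9)
  expect_equal(c(p2$lambda, p2$K), c(1.3, 0.5))
  expect_warning(
    pf <- lookup_karlin_params("blastn", reward = 9, penalty = -9,
                               gap_open = 1, gap_extend = 1,
                               stats_lambda = 1.1, stats_K = 0.3,
                               stats_H = 0.8),
    "ungapped convention")
  expect_equal(pf$alpha, 1.1 / 0.8)
  expect_equal(pf$beta, 0)
  expect_error(lookup_karlin_params("blastn", reward = 9, penalty = -9,
                                    gap_open = 1, gap_extend = 1),
               class = "incblast_lookup_error")
})
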