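sex_fixture <- function() {
  data.frame(
    male = rep(c(1, 0), c(738, 670)),
    outcome = c(rep(c(0, 1), c(560, 178)), rep(c(0, 1), c(483, 187))))
}

test_that("binary screening uses the Yates-corrected chi-square", {
  res <- univariate_screen(sex_fixture(), "male")
  expect_equal(round(res$p_value, 3), 0.119)
  expect_true(res$eligible)  # 0.119 < 0.50
  # agreement with the contingency-formula oracle
  tab <- matrix(c(560, 178, 483, 187), nrow = 2, byrow = TRUE)
  expect_equal(res$p_value, oracle_yates_p(tab), tolerance = 1e-8)
})

test_that("screening handles degenerate and balanced variables", {
  co <- data.frame(flag = rep(1, 100), outcome = rep(c(0, 1), 50))
  expect_warning(res <- univariate_screen(co, "flag"), "constant")
  expect_true(is.na(res$p_value))
  expect_false(res$eligible)

  balanced <- data.frame(x = rep(c(0, 1), 200),
                         outcome = rep(c(0, 1, 1, 0), 100))
  res <- univariate_screen(balanced, "x")
  expect_gt(res$p_value, 0.95)
  expect_false(res$eligible)

  # continuous variable takes the rank-sum branch
  set.seed(81)
  cont <- data.frame(age = c(rnorm(150, 60, 10), rnorm(150, 70, 10)),
                     outcome = rep(c(0, 1), each = 150))
  res <- univariate_screen(cont, "age")
  expect_equal(res$test, "Wilcoxon-Mann-Whitney")
  expect_lt(res$p_value, 0.001)
})

test_that("screen_predictors assembles a per-variable report", {
  co <- make_test_cohort(1500, seed = 82)
  rep_tab <- screen_predictors(co)
  expect_true(all(c("variable", "test", "p_value", "eligible") %in%
                    names(rep_tab)))
  expect_false(any(c("patient_id", "outcome", "true_p") %in%
                     rep_tab$variable))
  expect_true(all(rep_tab$p_value >= 0 & rep_tab$p_value <= 1, na.rm = TRUE))
  # n_drugs is a strong predictor under the generating model
  expect_lt(rep_tab$p_value[rep_tab$variable == "n_drugs"], 1e-4)
})

test_that("rule mining equals brute-force enumeration on toy transactions", {
  tx <- list(c("atc_B01", "atc_N05", "significant_me"),
             c("atc_B01", "significant_me"),
             c("atc_B01"),
             c("atc_N05"),
             c("atc_J01", "atc_B01", "significant_me"),
             c("atc_J01"),
             character(0),
             c("atc_N05", "atc_J01"),
             c("atc_B01", "atc_N05"),
             c("significant_me"))
  cfg <- screening_config(min_support = 0.1, min_confidence = 0.3)
  got <- mine_rules(tx, cfg)
  want <- oracle_rules(tx, 0.1, 0.3)
  expect_equal(got, want, ignore_attr = TRUE)

  # invariant to transaction order
  set.seed(83)
  expect_equal(mine_rules(tx[sample(length(tx))], cfg), got,
               ignore_attr = TRUE)

  # support above the maximum item frequency leaves nothing
  expect_equal(nrow(mine_rules(tx, screening_config(min_support = 0.9))), 0)
  expect_equal(nrow(mine_rules(list(), cfg)), 0)
})

test_that("a single always-co-occurring item yields its definitional rule", {
  tx <- c(replicate(4, c("atc_X", "significant_me"), simplify = FALSE),
          replicate(6, "atc_Y", simplify = FALSE))
  got <- mine_rules(tx, screening_config(min_support = 0.05,
                                         min_confidence = 0.10))
  x_rule <- got[got$antecedent == "atc_X", ]
  expect_equal(x_rule$support, 0.4)
  expect_equal(x_rule$confidence, 1)
})

test_that("raising thresholds never adds rules (anti-monotonicity)", {
  set.seed(84)
  co <- make_test_cohort(400, seed = 84)
  tx <- atc_transactions(co)
  loose <- mine_rules(tx, screening_config(min_support = 0.02,
                                           min_confidence = 0.05))
  for (s in c(0.05, 0.10, 0.20)) {
    for (cf in c(0.10, 0.30, 0.60)) {
      tight <- mine_rules(tx, screening_config(min_support = s,
                                               min_confidence = cf))
      expect_true(all(tight$antecedent %in% loose$antecedent))
    }
  }
})

test_that("candidate-class selection is a set union over retained rules", {
  expect_equal(select_candidate_classes(
    mine_rules(list(), screening_config())), character(0))

  # fixture engineered so exactly the five screened classes pass
  classes <- c("atc_B01", "atc_J01", "atc_N05", "atc_B05", "atc_N02")
  tx <- list()
  for (cl in classes) {
    tx <- c(tx,
            replicate(10, c(cl, "significant_me"), simplify = FALSE),
            replicate(10, cl, simplify = FALSE))
  }
  # a sixth class common but almost never with the endpoint
  tx <- c(tx, replicate(38, "atc_A02", simplify = FALSE),
          replicate(2, c("atc_A02", "significant_me"), simplify = FALSE))
  got <- select_candidate_classes(mine_rules(tx, screening_config()))
  expect_setequal(got, classes)

  # duplicated antecedent items collapse to a set
  rules <- data.frame(antecedent = c("atc_B01", "atc_B01+atc_N05"),
                      support = c(0.2, 0.1), confidence = c(0.5, 0.5),
                      n_antecedent = c(1, 2))
  expect_setequal(select_candidate_classes(rules), c("atc_B01", "atc_N05"))
})
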