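test_that("euclidean distance is a metric on patterns", {
  expect_equal(euclidean_distance(rep(1, 6), rep(1, 6)), 0)
  expect_equal(euclidean_distance(
    c(0.6, 0.8, 0, 0, 0, 0),
    rep(0, 6)
  ), 1.0)
  expect_error(euclidean_distance(1:5, 1:6), "length")
  # symmetry and triangle inequality on random triples
  set.seed(21)
  for (i in 1:25) {
    a <- runif(6)
    b <- runif(6)
    c <- runif(6)
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
    expect_lte(
      euclidean_distance(a, c),
      euclidean_distance(a, b) + euclidean_distance(b, c) + 1e-12
    )
  }
})

test_that("gray grade is xi at zero distance and strictly decreasing", {
  expect_equal(gray_grade(0, 3.2), 3.2)
  expect_equal(gray_grade(0.5, 7.9883), 0.1471692, tolerance = 1e-6)
  expect_error(gray_grade(0.5, 0), "xi")
  set.seed(22)
  xi <- runif(20, 0.1, 20)
  ed <- sort(runif(50, 0, 5))
  for (x in xi) {
    rho <- gray_grade(ed, x)
    expect_true(all(rho > 0 & rho <= x))
    expect_true(all(diff(rho) < 0))
  }
})

test_that("class averages and extremes follow the grouped means", {
  rho <- c(4, 2, 1, 3, 3, 3)
  cls <- c("I", "I", "II", "III", "III", "III")
  cag <- class_average_grades(rho, cls)
  expect_equal(cag$rho_ave, c(I = 3, II = 1, III = 3))
  expect_equal(cag$rho_min, 1)
  expect_equal(cag$rho_max, 3)
  # all equal grades collapse the extremes
  cag2 <- class_average_grades(rep(2, 6), cls)
  expect_equal(cag2$rho_min, cag2$rho_max)
  expect_error(class_average_grades(1:3, c("I", "I", "II")), "every class")
})

test_that("HSV transform normalizes channels and places hue in the right sector", {
  ave <- c(I = 0.9, II = 0.3, III = 0.1)
  h1 <- hsv_transform(ave, convention = "as_printed")
  expect_equal(h1$r, 1)
  expect_equal(h1$g, 0)
  expect_equal(h1$b, 0.75)
  expect_equal(h1$H, 105) # 60 * (b - r) + 120
  expect_equal(h1$S, 8 / 9)
  expect_equal(h1$gamma, 0.9)
  h2 <- hsv_transform(ave, convention = "class_centered")
  expect_equal(h2$H, 225) # 60 * (b - r) + 240, blue sector for Class I
  # degenerate case
  expect_error(hsv_transform(c(0.4, 0.4, 0.4)), "degenerate")
  # scaling all class means leaves r, g, b, H, S unchanged; gamma scales
  h3 <- hsv_transform(10 * ave, convention = "as_printed")
  expect_equal(
    h3[c("r", "g", "b", "H", "S")],
    h1[c("r", "g", "b", "H", "S")]
  )
  expect_equal(h3$gamma, 9)
})

test_that("nondegenerate transforms always pin one channel at 0 and one at 1", {
  set.seed(23)
  for (i in 1:50) {
    ave <- runif(3, 0.01, 5)
    if (max(ave) == min(ave)) next
    for (conv in c("class_centered", "as_printed")) {
      h <- hsv_transform(ave, convention = conv)
      ch <- c(h$r, h$g, h$b)
      expect_true(all(ch >= 0 & ch <= 1))
      expect_equal(min(ch), 0)
      expect_equal(max(ch), 1)
      expect_true(h$H >= 0 && h$H < 360)
      expect_true(h$S > 0 && h$S <= 1)
      expect_true(hue_to_hc(h$H) >= 0 && hue_to_hc(h$H) < 1)
    }
  }
})

test_that("hue decision variable is hue / 360", {
  expect_equal(hue_to_hc(240), 2 / 3)
  expect_equal(hue_to_hc(120), 1 / 3)
  expect_equal(hue_to_hc(0), 0)
  expect_error(hue_to_hc(361), "360")
})

test_that("self-classification recovers the class of a training pattern", {
  fix <- make_separated_training()
  for (conv in c("class_centered", "as_printed")) {
    model <- cra_model(fix$patterns, fix$classes,
      xi = 5,
      convention = conv
    )
    for (i in seq_len(nrow(fix$patterns))) {
      res <- classify_pattern(fix$patterns[i, ], model)
      expect_false(res$unclassifiable)
      expect_identical(
        as.character(res$predicted_class),
        as.character(fix$classes[i])
      )
    }
  }
})

test_that("classification is invariant to duplicating the training set", {
  fix <- make_separated_training()
  m1 <- cra_model(fix$patterns, fix$classes, xi = 5)
  m2 <- cra_model(
    rbind(fix$patterns, fix$patterns),
    c(fix$classes, fix$classes),
    xi = 5
  )
  query <- fix$patterns[5, ] + 0.01
  r1 <- classify_pattern(query, m1)
  r2 <- classify_pattern(query, m2)
  expect_equal(r1$H, r2$H)
  expect_equal(r1$rho_ave, r2$rho_ave)
  expect_identical(r1$predicted_class, r2$predicted_class)
})

test_that("hue angles land in each class's color sector (blue/green/red)", {
  fix <- make_separated_training()
  model <- cra_model(fix$patterns, fix$classes, xi = 8)
  proto <- class_prototypes()
  h_i <- classify_pattern(proto["I", ] + 0.005, model)$H
  h_ii <- classify_pattern(proto["II", ] + 0.005, model)$H
  h_iii <- classify_pattern(proto["III", ] + 0.005, model)$H
  expect_lt(abs(h_i - 240), 60) # Class I: blue
  expect_lt(abs(h_ii - 120), 60) # Class II: green
  expect_lt(min(h_iii, 360 - h_iii), 60) # Class III: red, wraps at 0/360
})

test_that("msef measures squared hue errors, wrapped and plain", {
  expect_equal(msef(c(2 / 3, 1 / 3, 1), c("I", "II", "III")), 0)
  expect_equal(msef(0.03, "III", error_mode = "wrapped"), 0.0009)
  expect_equal(msef(0.03, "III", error_mode = "plain"), 0.9409)
  expect_error(msef(numeric(0), character(0)), "empty")
  # wrapped error never exceeds plain error
  set.seed(24)
  hc <- runif(100)
  cls <- sample(c("I", "II", "III"), 100, replace = TRUE)
  expect_lte(msef(hc, cls, "wrapped"), msef(hc, cls, "plain"))
  for (i in 1:10) {
    h <- runif(5)
    cl <- sample(c("I", "II", "III"), 5, replace = TRUE)
    expect_lte(msef(h, cl, "wrapped"), msef(h, cl, "plain") + 1e-12)
  }
})

test_that("evaluation reports accuracy consistent with the confusion table", {
  fix <- make_separated_training()
  model <- cra_model(fix$patterns, fix$classes, xi = 5)
  ev <- cra_evaluate(model, fix$patterns, fix$classes)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(sum(ev$confusion), ev$n)
  expect_equal(as.vector(rowSums(ev$confusion)), as.vector(table(fix$classes)))
  expect_equal(sum(diag(ev$confusion)) / ev$n, ev$accuracy)
})

test_that("degenerate queries are flagged unclassifiable, not mislabelled", {
  # one pattern per class at exactly the same location: any query is
  # equidistant, the class means coincide, and the hue is undefined
  pat <- matrix(rep(c(1, 1, 1, 0.5, 0.5, 0.5), 3),
    nrow = 3, byrow = TRUE
  )
  model <- cra_model(pat, c("I", "II", "III"), xi = 2)
  res <- classify_pattern(c(1, 1, 1, 0.6, 0.6, 0.6), model)
  expect_true(res$unclassifiable)
  expect_true(is.na(res$predicted_class))
})
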