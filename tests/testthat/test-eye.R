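test_that("step-1 rules reproduce the published genotype combinations", {
  cases <- list(
    # label, genotypes
    list("blue",      list(rs12913832 = "G/G", rs12203592 = "T/T")),
    list("brown",     list(rs12913832 = "A/A", rs16891982 = "C/C")),
    list("brown",     list(rs12913832 = "A/G", rs6119471 = "G/G")),
    list("green",     list(rs12913832 = "A/G", rs12203592 = "T/T")),
    list("green",     list(rs12913832 = "G/G", rs16891982 = "C/C")),
    list("not_brown", list(rs12913832 = "G/G", rs16891982 = "C/G",
                           rs6119471 = "C/G", rs12203592 = "C/T",
                           rs12896399 = "G/T")),
    list("not_blue",  list(rs12913832 = "A/A")),
    list("not_blue",  list(rs12913832 = "A/G")),
    list("no_call",   list(rs12203592 = "T/T")))
  for (cs in cases) {
    out <- predict_eye_step1(do.call(mk_geno, cs[[2]]))
    expect_equal(out$eye_label, cs[[1]],
                 label = paste(names(cs[[2]]), unlist(cs[[2]]),
                               collapse = " "))
  }
})

test_that("simultaneously satisfiable rules are flagged and resolved by precedence", {
  # green + blue both fire: precedence picks green, conflict is flagged
  out <- predict_eye_step1(mk_geno(rs12913832 = "G/G", rs16891982 = "C/C",
                                   rs12203592 = "T/T"))
  expect_equal(out$eye_label, "green")
  expect_true(out$conflict)
  expect_equal(out$fired_rules, "green;blue")
  # brown + green both fire: brown wins
  out <- predict_eye_step1(mk_geno(rs12913832 = "A/G", rs16891982 = "C/C",
                                   rs12203592 = "T/T"))
  expect_equal(out$eye_label, "brown")
  expect_true(out$conflict)
  expect_equal(out$fired_rules, "brown;green")
})

test_that("step 2 upgrades only unrefined rs12913832 homozygotes", {
  out <- predict_eye(mk_geno(rs12913832 = "G/G", rs12203592 = "C/T",
                             rs12896399 = "T/T"))
  expect_equal(out$eye_label, "blue")
  expect_equal(out$eye_step, 2L)
  out <- predict_eye(mk_geno(rs12913832 = "A/A", rs16891982 = "C/G",
                             rs6119471 = "C/G", rs12896399 = "G/G"))
  expect_equal(out$eye_label, "brown")
  expect_equal(out$eye_step, 2L)
  # heterozygous rs12913832 keeps its baseline regardless of rs12896399
  out <- predict_eye(mk_geno(rs12913832 = "A/G", rs12896399 = "G/G"))
  expect_equal(out$eye_label, "not_blue")
  expect_equal(out$eye_step, 1L)
  # 7plex mode is exactly step 1
  g <- mk_geno(rs12913832 = "G/G", rs12203592 = "C/T", rs12896399 = "T/T")
  expect_equal(predict_eye(g, mode = "7plex"), predict_eye_step1(g))
  expect_error(predict_eye(g, mode = "9plex"))
})

test_that("every complete eye genotype vector gets exactly one label (100% call rate)", {
  g <- enumerate_trait("eye")
  expect_equal(nrow(g), 243L)
  s1 <- predict_eye_step1(g)
  s2 <- predict_eye(g, mode = "8plex")
  expect_false(any(s2$eye_label == "no_call"))
  expect_true(all(s2$eye_label %in%
                  c("brown", "green", "blue", "not_blue", "not_brown")))
  # step 2 never changes a positive step-1 label, and only upgrades
  # not_brown -> blue or not_blue -> brown
  pos1 <- s1$eye_label %in% c("brown", "green", "blue")
  expect_identical(s2$eye_label[pos1], s1$eye_label[pos1])
  changed <- s2$eye_label != s1$eye_label
  expect_true(all(s2$eye_step[changed] == 2L))
  expect_true(all(paste(s1$eye_label, s2$eye_label)[changed] %in%
                  c("not_brown blue", "not_blue brown")))
  # final positive labels stay compatible with the step-1 baseline:
  # blue only out of not_brown territory, brown only out of not_blue
  base <- ifelse(g$rs12913832 == "G/G", "not_brown", "not_blue")
  fin <- s2$eye_label
  expect_true(all(fin[fin == "blue"] == "blue" &
                  base[fin == "blue"] == "not_brown"))
  expect_true(all(base[fin == "brown"] == "not_blue"))
})

test_that("without rs12896399 the 8-plex collapses to the 7-plex", {
  g <- enumerate_trait("eye")
  g$rs12896399 <- NA_character_
  expect_equal(predict_eye(g, mode = "8plex"),
               predict_eye(g, mode = "7plex"))
})
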