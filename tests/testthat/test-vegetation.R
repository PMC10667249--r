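test_that("cover-type classification follows the survey rules and boundaries", {
  expect_equal(classify_plot(16, 0), "bare")
  expect_equal(classify_plot(67, 37), "shrubs")
  expect_equal(classify_plot(47, 5), "herbaceous")
  expect_equal(classify_plot(0, 0, open_water = TRUE), "open_water")
  # bare rule is applied before the shrub rule
  expect_equal(classify_plot(18, 21), "bare")
  # boundaries: exactly 20% vascular is not bare; exactly 20% shrub not shrubs
  expect_equal(classify_plot(20, 0), "herbaceous")
  expect_equal(classify_plot(50, 20), "herbaceous")
  expect_error(classify_plot(120, 0))
})

test_that("sector cover weights are plot-count proportions", {
  w <- cover_weights(c(rep("bare", 41), rep("herbaceous", 9)))
  expect_equal(unname(w["bare"]), 0.82)
  expect_equal(unname(w["herbaceous"]), 0.18)
  expect_equal(sum(w), 1)
  expect_equal(unname(cover_weights("shrubs")), 1)
  expect_equal(unname(cover_weights(c("bare", "shrubs"))), c(0.5, 0.5))
  expect_error(cover_weights(character(0)), "at least one")
})

test_that("classification and weights are order-invariant", {
  set.seed(5)
  types <- sample(c(rep("bare", 7), rep("herbaceous", 11), rep("shrubs", 2)))
  w1 <- cover_weights(types)
  w2 <- cover_weights(rev(types))
  expect_equal(w1[sort(names(w1))], w2[sort(names(w2))])
})

test_that("weighted sector means are convex combinations of per-type means", {
  expect_equal(weighted_sector_mean(c(bare = 170, herbaceous = -181),
                                    c(bare = 0.82, herbaceous = 0.18)), 106.82)
  # all types equal -> any weights give that value
  expect_equal(weighted_sector_mean(c(a = 5, b = 5, c = 5),
                                    c(a = 0.2, b = 0.5, c = 0.3)), 5)
  expect_error(weighted_sector_mean(c(a = 1), c(b = 1)), "do not match")
  expect_error(weighted_sector_mean(c(a = 1, b = 2), c(a = 0.6, b = 0.6)),
               "sum to 1")
})

test_that("habitat summary averages summed species cover over all plots", {
  lookup <- data.frame(species = c("sp_peat", "sp_wet"),
                       habitat = c("peatland", "wetland"),
                       growth_form = c("vascular", "vascular"))
  # one plot, one peatland species at 30%
  one <- data.frame(sector_id = "S", plot_id = "P1", species = "sp_peat",
                    cover_pct = 30)
  h1 <- habitat_summary(one, lookup)
  expect_equal(h1$mean_cover_pct[h1$habitat == "peatland"], 30)
  # two plots with peatland covers 10 and 30 -> mean 20
  two <- data.frame(sector_id = "S", plot_id = c("P1", "P2"),
                    species = "sp_peat", cover_pct = c(10, 30))
  h2 <- habitat_summary(two, lookup)
  expect_equal(h2$mean_cover_pct, 20)
  # a plot without species of a category still counts in the denominator
  three <- rbind(two, data.frame(sector_id = "S", plot_id = "P3",
                                 species = "sp_wet", cover_pct = 12))
  h3 <- habitat_summary(three, lookup)
  expect_equal(h3$mean_cover_pct[h3$habitat == "peatland"], 40 / 3)
  expect_equal(h3$mean_cover_pct[h3$habitat == "wetland"], 4)
  # unknown species are warned about and excluded
  four <- rbind(two, data.frame(sector_id = "S", plot_id = "P1",
                                species = "mystery", cover_pct = 50))
  expect_warning(h4 <- habitat_summary(four, lookup), "mystery")
  expect_equal(h4$mean_cover_pct, 20)
})

test_that("vegetation volume index averages band obstruction over sticks", {
  expect_equal(vegetation_volume_index(list(c(0, 0, 0))), 0)
  expect_equal(vegetation_volume_index(list(rep(100, 5), rep(100, 5))), 100)
  expect_equal(vegetation_volume_index(list(c(10, 30), c(40, 40))), 30)
  expect_error(vegetation_volume_index(list(c(10, 130))), "\\[0, 100\\]")
  expect_error(vegetation_volume_index(list()), "at least one")
})

test_that("sector summaries match two-pass statistics and stay convex", {
  budgets <- rbind(
    data.frame(collar_id = paste0("A", 1:3), sector_id = "S1", cover_type = "bare",
               nee_total = c(100, 150, 200), ch4_total = c(1, 2, 3),
               c_total = c(28, 42, 57), gwp = c(127, 204, 281)),
    data.frame(collar_id = paste0("B", 1:3), sector_id = "S1",
               cover_type = "herbaceous",
               nee_total = c(-400, -500, -600), ch4_total = c(8, 10, 12),
               c_total = c(-103, -129, -155), gwp = c(-184, -230, -276)))
  weights <- list(S1 = c(bare = 0.25, herbaceous = 0.75))
  s <- sector_summary(budgets, weights)
  bare <- s[s$cover_type == "bare", ]
  # two-pass standard deviation oracle
  x <- c(100, 150, 200)
  expect_equal(bare$nee_total_sd, sqrt(sum((x - mean(x))^2) / 2))
  expect_equal(bare$nee_total_mean, 150)
  all_row <- s[s$cover_type == "ALL", ]
  expect_equal(all_row$nee_total_mean, 0.25 * 150 + 0.75 * -500)
  # weighted mean lies within the range of per-type means
  per_type <- s$nee_total_mean[s$cover_type != "ALL"]
  expect_gte(all_row$nee_total_mean, min(per_type))
  expect_lte(all_row$nee_total_mean, max(per_type))
})

test_that("a single-cover-type sector's ALL row equals that type's row", {
  budgets <- data.frame(collar_id = paste0("A", 1:3), sector_id = "S1",
                        cover_type = "herbaceous",
                        nee_total = c(-400, -500, -600), ch4_total = c(8, 10, 12),
                        c_total = c(-103, -129, -155), gwp = c(-184, -230, -276))
  s <- sector_summary(budgets, list(S1 = c(herbaceous = 1)))
  expect_equal(s$nee_total_mean[s$cover_type == "ALL"],
               s$nee_total_mean[s$cover_type == "herbaceous"])
})
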