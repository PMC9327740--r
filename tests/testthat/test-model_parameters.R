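# The published input table, re-typed here independently of the package's
# internal definition, so any drift in the packaged base case is caught.
published_inputs <- read.csv(text = "name,base,low,high
init_within_intervention,0.9942,0.8948,1.0937
init_below_intervention,0.0029,0.0026,0.0032
init_above_intervention,0.0029,0.0026,0.0032
init_within_control,0.9855,0.8869,1.0840
init_below_control,0.0058,0.0052,0.0063
init_above_control,0.0087,0.0079,0.0096
p_within_to_below_intervention,0.0225,0.0203,0.0248
p_within_to_above_intervention,0.0191,0.0172,0.0210
p_below_to_within_intervention,0.4263,0.3837,0.4689
p_above_to_within_intervention,0.5712,0.5141,0.6283
p_within_to_below_control,0.0741,0.0667,0.0815
p_within_to_above_control,0.0383,0.0345,0.0421
p_below_to_within_control,0.1589,0.1430,0.1748
p_above_to_within_control,0.2910,0.2619,0.3201
p_above_to_bleeding,0.0115,0.0104,0.0127
p_below_to_te,0.0023,0.0021,0.0025
p_te_to_bleeding,0.00228,0.00205,0.00251
p_te_to_reoperation,0.00033,0.00030,0.00037
p_te_to_death,0.00374,0.00337,0.00412
p_te_to_te,0.08825,0.07942,0.09707
p_bleeding_to_te,0.00059,0.00053,0.00064
p_bleeding_to_reoperation,0.00033,0.00030,0.00037
p_bleeding_to_death,0.01078,0.00971,0.01186
p_bleeding_to_bleeding,0.02049,0.01844,0.02254
p_reop_to_te,0.00014,0.00012,0.00015
p_reop_to_bleeding,0.00028,0.00025,0.00031
p_reop_to_death,0.00035,0.00031,0.00038
p_reop_to_reop,0.00033,0.00030,0.00037
p_recovery_to_te,0.00059,0.00025,0.00109
p_recovery_to_bleeding,0.00228,0.00109,0.00532
p_recovery_to_reoperation,0.00033,0.00017,0.00075
p_recovery_to_death,0.00147,0.00131,0.00163
rr_death_major_te,2.25,1.75,2.75
rr_death_major_bleeding,1.5,1.0,2.0
u_within_range,0.987,0.967,0.998
u_bleeding,0.54,0.44,0.74
u_te,0.45,0.35,0.55
u_reoperation,0.45,0.35,0.75
u_recovery,0.668,0.61,0.76
c_bleeding,2777.78,2500.00,3055.56
c_te,2314.81,2083.33,2546.30
c_reoperation,16203.70,14583.33,17824.07
discount_rate_cost,0.035,0.02,0.06
discount_rate_qaly,0.035,0.02,0.06",
  stringsAsFactors = FALSE)

test_that("packaged base case carries every published input verbatim", {
  cfg <- default_base_case()
  expect_setequal(names(cfg$params), published_inputs$name)
  for (i in seq_len(nrow(published_inputs))) {
    p <- cfg$params[[published_inputs$name[i]]]
    expect_identical(p$base, published_inputs$base[i],
                     info = published_inputs$name[i])
    expect_identical(p$low, published_inputs$low[i],
                     info = published_inputs$name[i])
    expect_identical(p$high, published_inputs$high[i],
                     info = published_inputs$name[i])
  }
  # spot values with their own meaning: a probability, a risk ratio, a sum
  expect_equal(cfg$params$p_within_to_below_intervention$base, 0.0225)
  expect_equal(cfg$params$rr_death_major_te$base, 2.25)
  expect_equal(cfg$params$init_within_control$base +
                 cfg$params$init_below_control$base +
                 cfg$params$init_above_control$base, 1.0)
  expect_equal(cfg$params$init_within_intervention$base +
                 cfg$params$init_below_intervention$base +
                 cfg$params$init_above_intervention$base, 1.0)
})

test_that("packaged fixture file round-trips to the base case", {
  fixture <- system.file("extdata", "base_case_table1.json",
                         package = "warfarinCEA")
  expect_true(nzchar(fixture))
  cfg <- load_config(fixture)
  expect_equal(cfg, default_base_case())
  # and a serialise -> parse round trip through both dialects
  for (ext in c("json", "yaml")) {
    tmp <- tempfile(fileext = paste0(".", ext))
    write_config(default_base_case(), tmp)
    expect_equal(load_config(tmp), default_base_case())
    unlink(tmp)
  }
})

test_that("config validation rejects out-of-bound and infeasible inputs", {
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(p_within_to_below_intervention = 1.2), bad,
                       auto_unbox = TRUE)
  expect_error(suppressWarnings(load_config(bad)),
               "p_within_to_below_intervention")
  jsonlite::write_json(list(p_within_to_below_intervention = 0.6,
                            p_within_to_above_intervention = 0.5), bad,
                       auto_unbox = TRUE)
  expect_error(suppressWarnings(load_config(bad)), "WithinRange")
  jsonlite::write_json(list(p_te_to_death = list(low = 0.1, high = 0.2)), bad,
                       auto_unbox = TRUE)
  expect_error(suppressWarnings(load_config(bad)), "base")
  jsonlite::write_json(list(not_a_parameter = 0.1), bad, auto_unbox = TRUE)
  expect_error(load_config(bad), "unknown parameter")
  unlink(bad)
  # partial configs fall back to the packaged base case, with a warning
  part <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(u_bleeding = 0.6), part)
  expect_warning(cfg <- load_config(part), "falling back")
  expect_equal(cfg$params$u_bleeding$base, 0.6)
  expect_equal(cfg$params$u_te$base, 0.45)
  unlink(part)
})

test_that("parameter_value enforces range ordering", {
  expect_error(parameter_value(0.5, low = 0.6), "low <= base")
  expect_error(parameter_value(0.5, high = 0.4), "low <= base")
  p <- parameter_value(0.5)
  expect_equal(p$low, 0.5)
  expect_equal(p$high, 0.5)
})

test_that("parameter catalogue enumerates every ranged input", {
  cfg <- default_base_case()
  cat_df <- parameter_catalog(cfg)
  expect_gte(nrow(cat_df), 30)
  expect_equal(nrow(cat_df), nrow(published_inputs))
  dq <- cat_df[cat_df$name == "discount_rate_qaly", ]
  expect_equal(unlist(dq[c("base", "low", "high")], use.names = FALSE),
               c(0.035, 0.02, 0.06))
  # collapsing every range to the base value leaves a degenerate catalogue
  for (nm in cat_df$name)
    cfg <- set_parameter(cfg, nm, cat_df$base[cat_df$name == nm])
  flat <- parameter_catalog(cfg)
  expect_true(all(flat$low == flat$base & flat$high == flat$base))
})
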