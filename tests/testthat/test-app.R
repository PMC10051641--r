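# End-to-end plumbing with small untrained-but-seeded models: enrollment,
# verification and identification semantics do not depend on matcher quality,
# only on the pipeline being deterministic and the stores consistent.

make_tiny_system <- function(store) {
  ucfg <- unet_config(input_size = c(64, 64), base_filters = 4, depth = 2,
                      bottleneck_filters = 16, seed = 3)
  scfg <- siamese_config(input_size = c(64, 64), conv_filters = 8,
                         decision_threshold = 0.5, seed = 4)
  acfg <- app_config(template_store = store,
                     preprocess = preprocess_config(target_size = c(64, 64)),
                     unet = ucfg, siamese = scfg)
  vein_system(build_unet(ucfg), build_subnetwork(scfg), acfg)
}

test_that("app config round-trips through YAML unchanged", {
  cfg <- app_config(seed = 77,
                    preprocess = preprocess_config(target_size = c(128, 128)),
                    labeling = labeling_config(binarize_threshold = 25))
  path <- withr::local_tempfile(fileext = ".yaml")
  save_app_config(cfg, path)
  expect_equal(load_app_config(path), cfg)
})

test_that("model checkpoints round-trip with a JSON sidecar", {
  dir <- withr::local_tempdir()
  m <- build_unet(unet_config(input_size = c(32, 32), base_filters = 2,
                              depth = 2, bottleneck_filters = 4))
  p <- file.path(dir, "unet.rds")
  save_model(m, p)
  expect_true(file.exists(paste0(p, ".json")))
  m2 <- load_model(p)
  expect_identical(m2$params, m$params)
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_equal(side$class, "unet_model")
  expect_error(load_model(file.path(dir, "missing.rds")), "train")
})

test_that("enroll then verify the same image matches; unknown ids error", {
  store <- withr::local_tempdir()
  sys <- make_tiny_system(store)
  img <- fixture_dataset()$images[[1]]
  enroll(sys, img, "alice")
  dec <- verify(sys, img, "alice")
  expect_true(dec$verdict)
  expect_equal(dec$distance, 0, tolerance = 1e-6)
  expect_error(verify(sys, img, "mallory"), "not enrolled")
})

test_that("repeat enrollments are kept side by side", {
  store <- withr::local_tempdir()
  sys <- make_tiny_system(store)
  ds <- fixture_dataset()
  enroll(sys, ds$images[[1]], "bob")
  enroll(sys, ds$images[[2]], "bob")
  expect_length(list.files(file.path(store, "bob"), pattern = "\\.json$"), 2)
})

test_that("identification ranks the gallery and gates on the threshold", {
  store <- withr::local_tempdir()
  sys <- make_tiny_system(store)
  ds <- fixture_dataset()
  reg <- ds$registry
  s1 <- which(reg$session == 1)[1:4]
  for (i in s1)
    enroll(sys, ds$images[[i]], paste(reg$subject_id[i], reg$wrist[i], sep = "_"))
  expect_error(identify(make_tiny_system(withr::local_tempdir()),
                        ds$images[[1]]), "empty")
  res <- identify(sys, ds$images[[s1[1]]])
  expect_equal(res$top, paste(reg$subject_id[s1[1]], reg$wrist[s1[1]], sep = "_"))
  expect_true(res$accepted)   # identical probe: distance 0 passes any tau
  expect_equal(nrow(res$ranking), 4)
  expect_true(!is.unsorted(res$ranking$score))
})

test_that("verify agrees with identify on a single-identity gallery", {
  store <- withr::local_tempdir()
  sys <- make_tiny_system(store)
  ds <- fixture_dataset()
  enroll(sys, ds$images[[1]], "solo")
  probe <- ds$images[[3]]
  v <- verify(sys, probe, "solo")
  i <- identify(sys, probe)
  expect_equal(i$accepted, v$verdict)
  expect_equal(i$ranking$score[1], v$distance)
})

test_that("the CLI script is present and wired to the package", {
  cli <- system.file("cli", "wristvein.R", package = "wristvein")
  expect_true(nzchar(cli))
  src <- readLines(cli)
  expect_true(any(grepl("library\\(wristvein\\)", src)))
  for (sub in c("generate", "train-unet", "build-pairs", "train-matcher",
                "evaluate", "enroll", "verify", "identify"))
    expect_true(any(grepl(sub, src, fixed = TRUE)))
})
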