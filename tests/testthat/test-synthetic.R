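# Synthetic panoramic scene generator.

test_that("config validation enforces the invariants", {
  expect_error(gen_config(height = 0), "positive")
  expect_error(gen_config(height = 300, width = 200), "width >= height")
  expect_error(gen_config(p_filling = 1.2), "probabilities")
  sr <- rbind(filling = c(10, 20), crown = c(5, 30),
              root_canal = c(8, 40), implant = c(50, 60))
  expect_error(gen_config(size_ranges = sr), "root_canal")
})

test_that("identical (config, seed) give bit-identical output", {
  cfg <- tiny_gen_config()
  a <- generate_image(cfg, seed = 123)
  b <- generate_image(cfg, seed = 123)
  expect_identical(a, b)
  c <- generate_image(cfg, seed = 124)
  expect_false(identical(a$image, c$image))
})

test_that("probability-zero classes stay empty", {
  cfg <- tiny_gen_config(p_implant = 0)
  li <- generate_image(cfg, seed = 5)
  expect_equal(sum(li$mask[, , 4]), 0)
  cfg0 <- tiny_gen_config(p_filling = 0, p_crown = 0, p_root_canal = 0,
                          p_implant = 0)
  li0 <- generate_image(cfg0, seed = 5)
  expect_equal(sum(li0$mask), 0)
  expect_equal(nrow(li0$metadata), 0)
})

test_that("mask pixel counts equal the sum of metadata object areas", {
  cfg <- tiny_gen_config()
  for (seed in 1:10) {
    li <- generate_image(cfg, seed = seed)
    for (ch in 1:4) {
      meta_area <- sum(li$metadata$area[li$metadata$class ==
                                          CLASS_CHANNELS[ch]])
      expect_equal(sum(li$mask[, , ch]), meta_area,
                   info = paste("seed", seed, "channel", ch))
    }
  }
})

test_that("crown and root-canal channels overlap when both are certain", {
  # all-probability-one config over many teeth: the root-canal cone is
  # built to reach into the crown cap
  cfg <- gen_config(height = 128, width = 256, n_teeth = 20,
                    p_filling = 1, p_crown = 1, p_root_canal = 1,
                    p_implant = 0)
  overlap <- 0; rc_total <- 0
  for (seed in 1:50) {   # 1000 teeth in total
    li <- generate_image(cfg, seed = seed)
    overlap <- overlap + sum(li$mask[, , 2] & li$mask[, , 3])
    rc_total <- rc_total + sum(li$mask[, , 3])
  }
  expect_gt(overlap / rc_total, 0)
})

test_that("multi-label: some pixel belongs to 2+ channels in >=90% of images", {
  cfg <- gen_config(height = 128, width = 256, p_filling = 1, p_crown = 1,
                    p_root_canal = 1, p_implant = 1)
  hits <- vapply(1:100, function(seed) {
    li <- generate_image(cfg, seed = seed)
    any(apply(li$mask, c(1, 2), sum) >= 2)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("dataset generation is deterministic and extensible", {
  cfg <- tiny_gen_config()
  d1 <- generate_dataset(cfg, 5, seed = 7)
  d2 <- generate_dataset(cfg, 5, seed = 7)
  expect_identical(d1$images, d2$images)
  expect_identical(d1$manifest, d2$manifest)
  # extending the dataset does not reshuffle earlier images
  d3 <- generate_dataset(cfg, 7, seed = 7)
  expect_identical(d3$images[1:5], d1$images)
})

test_that("dataset files round-trip through PNG + manifest", {
  cfg <- tiny_gen_config()
  dir <- file.path(tempdir(), "tileseg-ds-test")
  unlink(dir, recursive = TRUE)
  ds <- generate_dataset(cfg, 3, seed = 2, out_dir = dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(man, 3)
  expect_length(man[[1]]$mask_paths, 4)
  expect_true(grepl("_rootcanal\\.png$", man[[1]]$mask_paths[[3]]))
  back <- load_dataset(dir)
  for (i in 1:3) {
    expect_identical(back$images[[i]]$image, ds$images[[i]]$image)
    expect_identical(back$images[[i]]$mask, ds$images[[i]]$mask)
  }
  # writing twice gives byte-identical files
  dir2 <- file.path(tempdir(), "tileseg-ds-test2")
  unlink(dir2, recursive = TRUE)
  generate_dataset(cfg, 3, seed = 2, out_dir = dir2)
  f1 <- file.path(dir, man[[1]]$image_path)
  f2 <- file.path(dir2, man[[1]]$image_path)
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
  unlink(dir, recursive = TRUE); unlink(dir2, recursive = TRUE)
})

test_that("class size and frequency structure match the intended ordering", {
  ds <- generate_dataset(desk_gen_config(), 100, seed = 31)
  rep <- class_frequency_report(ds)
  expect_equal(rep$channel, CLASS_CHANNELS)
  # root-canal fillings: smallest objects, well below filling and crown
  areas <- setNames(rep$mean_object_area, rep$channel)
  expect_lt(areas[["root_canal"]], areas[["filling"]])
  expect_lt(areas[["filling"]], areas[["crown"]])
  # prevalence: root canal below crown (smaller and rarer)
  prev <- setNames(rep$pixel_prevalence, rep$channel)
  expect_lt(prev[["root_canal"]], prev[["crown"]])
  # per-image object frequency: root canal < crown
  counts <- setNames(rep$object_count, rep$channel)
  expect_lt(counts[["root_canal"]], counts[["crown"]])
})

test_that("class_frequency_report arithmetic on a hand-built case", {
  img <- matrix(0L, 10, 10)
  mask <- array(0L, c(10, 10, 4))
  mask[1, 1:3, 1] <- 1L   # single 3-pixel filling object
  li <- structure(list(id = "x", image = img, mask = mask,
                       metadata = data.frame(class = "filling", tooth = 1,
                                             row_min = 1, row_max = 1,
                                             col_min = 1, col_max = 3,
                                             area = 3),
                       seed = 1L), class = "labeled_image")
  rep <- class_frequency_report(list(li))
  expect_equal(rep$pixel_prevalence[1], 0.03)
  expect_equal(rep$object_count[1], 1)
  expect_equal(rep$object_count[4], 0)
  expect_equal(rep$pixel_prevalence[4], 0)
})
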