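test_that("OBJ parsing honors v/f records, 1-based indices, fan triangulation", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("# comment", "v 0 0 0", "v 1 0 0", "v 0 1 0",
               "vn 0 0 1", "f 1 2 3"), p)
  m <- read_obj(p)
  expect_identical(nrow(m$vertices), 3L)
  expect_identical(m$faces, matrix(c(1L, 2L, 3L), 1L))

  # quad fan-triangulates by default, errors in strict mode
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"), p)
  expect_identical(nrow(read_obj(p)$faces), 2L)
  expect_error(read_obj(p, strict = TRUE), class = "parse_error")
})

test_that("malformed OBJ records raise parse errors naming the line", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2"), p)
  expect_error(read_obj(p), "line 4", class = "parse_error")
  writeLines(c("v 0 0 zebra"), p)
  expect_error(read_obj(p), "line 1", class = "parse_error")
  expect_error(read_obj("no/such/file.obj"), class = "io_error")
})

test_that("OBJ write-read round-trip preserves connectivity and coordinates", {
  tm <- make_template(6)
  p <- withr::local_tempfile(fileext = ".obj")
  write_obj(tm, p)
  back <- read_obj(p)
  expect_identical(back$faces, tm$faces)
  expect_equal(back$vertices, tm$vertices, tolerance = 1e-6)
  # read-write-read is the identity on the parsed representation
  p2 <- withr::local_tempfile(fileext = ".obj")
  write_obj(back, p2)
  again <- read_obj(p2)
  expect_identical(again$faces, back$faces)
  expect_equal(again$vertices, back$vertices, tolerance = 1e-12)
})

test_that("landmark CSV reading keeps file order, ignores extras, validates", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,x,y,z,comment",
               "tip,1,2,3,hello", "base,4,5,6,w", "left,7,8,9,x",
               "right,10,11,12,y"), p)
  lm <- read_landmarks_csv(p)
  expect_identical(lm$names, c("tip", "base", "left", "right"))
  expect_equal(lm$coordinates[2, ], c(4, 5, 6))

  writeLines(c("name,x,y,z", "a,1,2,3", "a,4,5,6", "b,0,0,1"), p)
  expect_error(read_landmarks_csv(p), class = "parse_error")
  writeLines(c("name,x,y,z", "a,1,2,three", "b,0,0,1"), p)
  expect_error(read_landmarks_csv(p), class = "parse_error")
})

test_that("vertex field writer emits neutral/diverging colors and exact CSV", {
  tm <- make_template(5)
  V <- nrow(tm$vertices)
  stem <- file.path(withr::local_tempdir(), "field")

  paths <- write_vertex_field(tm, rep(0, V), stem)
  ply <- readLines(paths[["ply"]])
  body <- ply[(which(ply == "end_header") + 1):(which(ply == "end_header") + V)]
  cols <- t(vapply(strsplit(body, " "), function(x) as.integer(x[4:6]),
                   integer(3)))
  expect_true(all(cols == 255L))   # all-zero field: neutral midpoint color

  field <- rep(0, V); field[7] <- 1
  paths <- write_vertex_field(tm, field, stem)
  ply <- readLines(paths[["ply"]])
  body <- ply[(which(ply == "end_header") + 1):(which(ply == "end_header") + V)]
  cols <- t(vapply(strsplit(body, " "), function(x) as.integer(x[4:6]),
                   integer(3)))
  expect_identical(cols[7, ], c(255L, 0L, 0L))      # strictly redder
  expect_lt(cols[7, 3], cols[1, 3])

  csv <- read.csv(paths[["csv"]])
  expect_equal(csv$value, as.numeric(sprintf("%.6f", field)))
  expect_error(write_vertex_field(tm, rep(0, V - 1), stem),
               class = "invalid_parameter")
})

test_that("manifest loading is fail-fast on labels and paths", {
  d <- withr::local_tempdir()
  tm <- make_template(4)
  write_obj(tm, file.path(d, "a.obj"))
  mpath <- file.path(d, "manifest.csv")
  writeLines(c("specimen_id,mesh_path,landmark_path,genotype,sex,litter",
               "s1,a.obj,a.csv,WT,M,L1",
               "s2,a.obj,a.csv,HET,F,L1"), mpath)
  mf <- read_manifest(mpath, genotype_levels = c("WT", "HET"))
  expect_identical(nrow(mf), 2L)
  expect_error(read_manifest(mpath, genotype_levels = c("WT", "KO")),
               class = "invalid_label")
  expect_error(read_manifest(mpath, genotype_levels = c("WT", "HET"),
                             sex_levels = c("F")), class = "invalid_label")
  writeLines(c("specimen_id,mesh_path,landmark_path,genotype,sex,litter",
               "s1,missing.obj,a.csv,WT,M,L1"), mpath)
  expect_error(read_manifest(mpath), "s1", class = "io_error")
})
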