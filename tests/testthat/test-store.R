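# Annotation store: mapping contract, spatial queries, predicate language,
# serialization, format conversions, backend equivalence.

both_backends <- function() {
  list(memory = open_store("memory"),
       database = open_store("database"))
}

test_that("both backends satisfy the mapping contract identically", {
  for (backend in c("memory", "database")) {
    s <- open_store(backend)
    a1 <- annotation(geom_point(3, 4), list(class = 1L))
    a2 <- annotation(geom_polygon(rbind(c(0, 0), c(10, 0), c(5, 8))),
                     list(class = 2L, prob = 0.25))
    k1 <- store_insert(s, a1)
    k2 <- store_insert(s, a2, key = "poly-1")
    expect_equal(store_length(s), 2)
    expect_equal(length(s), 2)
    expect_setequal(store_keys(s), c(k1, "poly-1"))

    got <- store_get(s, "poly-1")
    expect_true(geoms_equal(got$geometry, a2$geometry))
    expect_equal(got$properties$prob, 0.25)

    # overwrite semantics
    store_insert(s, a1, key = "poly-1")
    expect_equal(store_length(s), 2)
    expect_equal(geom_type(store_get(s, "poly-1")$geometry), "POINT")

    store_delete(s, k1)
    expect_equal(store_length(s), 1)
    expect_error(store_get(s, k1), class = "wsikit_key_error")
    expect_error(store_delete(s, k1), class = "wsikit_key_error")
    if (backend == "database") close_store(s)
  }
})

test_that("database stores persist across reopen", {
  path <- file.path(fixture_dir(), "persist.db")
  unlink(path)
  s <- open_store("database", path)
  anns <- make_annotations(100, c(0, 0, 500, 500), seed = 4)
  keys <- vapply(anns, function(a)
    store_insert(s, annotation(a$geometry, a$properties)), character(1))
  close_store(s)

  s2 <- open_store("database", path)
  expect_equal(store_length(s2), 100)
  for (k in keys[1:10]) {
    expect_true(geoms_equal(store_get(s2, k)$geometry,
                            anns[[match(k, keys)]]$geometry))
  }
  # spatial index also persisted
  expect_gt(length(bquery(s2, c(0, 0, 250, 250))), 0)
  close_store(s2)

  expect_error(open_store("database", "/nonexistent/deep/path/x.db"),
               class = "wsikit_format_error")
})

test_that("bounding-box queries equal the linear-scan oracle", {
  anns <- make_annotations(1000, c(0, 0, 4000, 3000), seed = 6)
  bboxes <- t(vapply(anns, function(a) geom_bbox(a$geometry), numeric(4)))
  ss <- both_backends()
  keys <- vapply(seq_along(anns), function(i) {
    k <- sprintf("a%04d", i)
    for (s in ss) store_insert(s, annotation(anns[[i]]$geometry,
                                             anns[[i]]$properties), key = k)
    k
  }, character(1))

  for (s in ss) {
    expect_length(bquery(s, c(-10, -10, -1, -1)), 0)
    expect_setequal(bquery(s, c(-1, -1, 4001, 3001)), keys)
  }
  set.seed(10)
  for (q in 1:40) {
    x0 <- runif(1, 0, 3500); y0 <- runif(1, 0, 2500)
    b <- c(x0, y0, x0 + runif(1, 50, 900), y0 + runif(1, 50, 900))
    want <- bbox_query_oracle(bboxes, keys, b)
    for (s in ss) expect_setequal(bquery(s, b), want)
  }
  close_store(ss$database)

  empty <- open_store("memory")
  expect_length(bquery(empty, c(0, 0, 10, 10)), 0)
})

test_that("polygon + predicate queries filter exactly, on both paths", {
  anns <- make_annotations(600, c(0, 0, 2000, 2000), seed = 8)
  ss <- both_backends()
  keys <- vapply(seq_along(anns), function(i) {
    k <- sprintf("a%04d", i)
    for (s in ss) store_insert(s, annotation(anns[[i]]$geometry,
                                             anns[[i]]$properties), key = k)
    k
  }, character(1))

  # L-shape: candidates in the bbox but outside the arms are excluded
  L <- geom_polygon(rbind(c(0, 0), c(900, 0), c(900, 300), c(300, 300),
                          c(300, 900), c(0, 900)))
  want <- keys[vapply(anns, function(a)
    geoms_intersect(a$geometry, L), logical(1))]
  for (s in ss) expect_setequal(names(store_query(s, L)), want)
  in_bbox_not_L <- keys[vapply(anns, function(a) {
    bbox_intersects(geom_bbox(a$geometry), geom_bbox(L)) &&
      !geoms_intersect(a$geometry, L)
  }, logical(1))]
  expect_gt(length(in_bbox_not_L), 0)  # the bbox prefilter alone would err

  # translatable predicate: SQL path vs interpreted oracle
  pred <- 'props[["class"]] == 2'
  want2 <- keys[vapply(anns, function(a)
    isTRUE(a$properties$class == 2), logical(1))]
  for (s in ss) {
    expect_setequal(names(store_query(s, NULL, pred)), want2)
  }
  expect_match(wsikit:::predicate_to_sql(predicate(pred)), "json_extract")

  # untranslatable predicate falls back silently to interpretation
  pred2 <- 'length(props[["class"]]) == 1 & props$prob > 0.5'
  expect_null(wsikit:::predicate_to_sql(predicate(pred2)))
  want3 <- keys[vapply(anns, function(a)
    isTRUE(a$properties$prob > 0.5), logical(1))]
  for (s in ss) expect_setequal(names(store_query(s, NULL, pred2)), want3)

  # trivial predicate equals no predicate
  for (s in ss) {
    expect_setequal(names(store_query(s, L, "TRUE")),
                    names(store_query(s, L)))
  }
  close_store(ss$database)
})

test_that("the predicate grammar rejects anything outside itself", {
  expect_error(predicate('system("ls")'), class = "wsikit_predicate_error")
  expect_error(predicate('props[["a"]] == 1; props'),
               class = "wsikit_predicate_error")
  expect_error(predicate('get("x")'), class = "wsikit_predicate_error")
  expect_error(predicate('x + 1'), class = "wsikit_predicate_error")
  expect_error(predicate('props[[paste("a")]]'),
               class = "wsikit_predicate_error")
  # allowed forms parse
  for (e in c('props$class %in% c(1, 2)', 'abs(props$x - 2) < 0.5',
              '!(props[["flag"]])', 'props$a + props$b >= 3')) {
    expect_s3_class(predicate(e), "wsi_predicate")
  }
  # missing properties never match, on either path
  s <- open_store("database")
  store_insert(s, annotation(geom_point(1, 1), list(class = 1)), "k1")
  expect_length(store_query(s, NULL, 'props$missing == 1'), 0)
  close_store(s)
})

test_that("WKB and compression round-trip losslessly", {
  anns <- make_annotations(50, c(0, 0, 1000, 1000), seed = 12,
                           point_fraction = 0.3)
  for (a in anns) {
    for (compress in c(FALSE, TRUE)) {
      back <- deserialize_geometry(serialize_geometry(a$geometry, compress))
      expect_true(geoms_equal(back, a$geometry))
    }
  }
  ring <- geom_ring(rbind(c(0, 0), c(5, 0), c(5, 5)))
  expect_true(geoms_equal(deserialize_geometry(serialize_geometry(ring)),
                          ring))

  big <- geom_polygon(cbind(500 + 400 * cos(seq(0, 2 * pi,
                                                length.out = 1001)[-1001]),
                            500 + 400 * sin(seq(0, 2 * pi,
                                                length.out = 1001)[-1001])))
  expect_lt(length(serialize_geometry(big, TRUE)),
            length(serialize_geometry(big, FALSE)))

  expect_error(deserialize_geometry(as.raw(c(1, 2, 3))),
               class = "wsikit_decode_error")

  # query results independent of the compression setting
  s_plain <- open_store("database", compress = FALSE)
  s_comp <- open_store("database", compress = TRUE)
  for (i in seq_along(anns)) {
    k <- sprintf("k%03d", i)
    store_insert(s_plain, annotation(anns[[i]]$geometry,
                                     anns[[i]]$properties), k)
    store_insert(s_comp, annotation(anns[[i]]$geometry,
                                    anns[[i]]$properties), k)
  }
  q <- geom_polygon(rbind(c(100, 100), c(600, 100), c(600, 600), c(100, 600)))
  expect_setequal(names(store_query(s_plain, q)),
                  names(store_query(s_comp, q)))
  close_store(s_plain); close_store(s_comp)
})

test_that("points store no geometry payload yet reconstruct exactly", {
  s <- open_store("database")
  k <- store_insert(s, annotation(geom_point(123.456789, -7.25),
                                  list(class = 3L)))
  row <- DBI::dbGetQuery(s$con,
    "SELECT (geometry IS NULL) AS no_blob FROM annotations WHERE key = ?",
    params = list(k))
  expect_equal(row$no_blob, 1L)
  g <- store_get(s, k)$geometry
  expect_identical(g$coords, matrix(c(123.456789, -7.25), 1))
  close_store(s)
})

test_that("format conversions round-trip annotations exactly", {
  anns <- make_annotations(80, c(0, 0, 800, 800), seed = 9,
                           point_fraction = 0.25)
  s <- open_store("memory")
  keys <- vapply(seq_along(anns), function(i)
    store_insert(s, annotation(anns[[i]]$geometry, anns[[i]]$properties),
                 sprintf("k%03d", i)), character(1))

  same_store <- function(s2) {
    all(vapply(keys, function(k) {
      a <- store_get(s, k); b <- store_get(s2, k)
      geoms_equal(a$geometry, b$geometry) &&
        identical(a$properties[order(names(a$properties))],
                  b$properties[order(names(b$properties))])
    }, logical(1)))
  }

  gj <- store_to_geojson(s)
  expect_true(jsonlite::validate(gj))
  expect_equal(jsonlite::fromJSON(gj, simplifyVector = FALSE)$type,
               "FeatureCollection")
  expect_true(same_store(store_from_geojson(gj)))

  nd <- store_to_ndjson(s)
  expect_length(nd, store_length(s))
  expect_true(same_store(store_from_ndjson(nd)))

  tab <- store_to_table(s)
  expect_equal(nrow(tab), 80)
  expect_true(all(c("key", "class", "prob") %in% names(tab)))

  mp <- store_to_mapping(s)
  expect_true(same_store(store_from_mapping(mp)))

  # database round trip through GeoJSON too
  sdb <- store_from_geojson(gj, store_out = open_store("database"))
  expect_true(same_store(sdb))
  close_store(sdb)

  expect_error(store_from_geojson('{"type": "bogus"}'),
               class = "wsikit_parse_error")
  expect_error(store_from_ndjson('{"not": "a feature"}'),
               class = "wsikit_parse_error")
})

test_that("random operation sequences leave both backends identical", {
  set.seed(20)
  ss <- both_backends()
  live <- character()
  counter <- 0L
  for (op in 1:2000) {
    r <- runif(1)
    if (r < 0.5 || length(live) == 0) {
      counter <- counter + 1L
      k <- sprintf("k%05d", counter)
      a <- annotation(geom_point(runif(1, 0, 1000), runif(1, 0, 1000)),
                      list(class = sample(1:3, 1)))
      for (s in ss) store_insert(s, a, k)
      live <- c(live, k)
    } else if (r < 0.7) {
      k <- sample(live, 1)
      for (s in ss) store_delete(s, k)
      live <- setdiff(live, k)
    } else if (r < 0.85) {
      b <- c(runif(1, 0, 900), runif(1, 0, 900), 0, 0)
      b[3] <- b[1] + runif(1, 10, 300); b[4] <- b[2] + runif(1, 10, 300)
      expect_setequal(bquery(ss$memory, b), bquery(ss$database, b))
    } else {
      expect_equal(store_length(ss$memory), store_length(ss$database))
    }
  }
  expect_setequal(store_keys(ss$memory), store_keys(ss$database))
  close_store(ss$database)
})

test_that("indexed window queries touch a small candidate set", {
  # uniform fixture; a ~1%-area window's R-Tree candidates stay below 5%
  s <- open_store("database")
  set.seed(30)
  n <- 4000
  for (i in 1:n) {
    cx <- runif(1, 0, 1000); cy <- runif(1, 0, 1000)
    poly <- geom_polygon(cbind(cx + c(0, 4, 4, 0), cy + c(0, 0, 4, 4)))
    store_insert(s, annotation(poly, list()), sprintf("k%05d", i))
  }
  hits <- length(bquery(s, c(500, 500, 600, 600)))
  expect_lt(hits / n, 0.05)
  close_store(s)
})
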