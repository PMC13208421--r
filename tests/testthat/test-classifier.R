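test_that("the three species average profiles route to themselves", {
  pulv <- classifyMicroscopy(4.87, 12.29, "narrowly_amygdaliform", 3.5,
                             "sparse")
  expect_identical(keyLabel(pulv), "pulverulentus")
  expect_identical(pathString(pulv), "1a→2b→3b")

  medi <- classifyMicroscopy(5.33, 12.67, "narrowly_subamygdaliform", 1.8,
                             "sparse")
  expect_identical(keyLabel(medi), "mediterraneensis")
  expect_identical(pathString(medi), "1b→4b→5b")

  poik <- classifyMicroscopy(5.03, 11.83, "ellipsoid_blunt", 1.0, "abundant")
  expect_identical(keyLabel(poik), "poikilochromus")
  expect_identical(pathString(poik), "1b→4a")
})

test_that("the key's printed gaps stay indeterminate", {
  # depression between the shallow and pronounced bounds
  gap <- classifyMicroscopy(5.4, 12.6, "narrowly_subamygdaliform", 2.7,
                            "sparse")
  expect_identical(keyLabel(gap), "indeterminate")
  expect_setequal(keyCandidates(gap), c("pulverulentus", "mediterraneensis"))
  expect_identical(pathString(gap), "1b→4b→5?")

  # width exactly on the couplet-1 split
  w5 <- classifyMicroscopy(5, 12.5, "narrowly_amygdaliform", 4, "sparse")
  expect_identical(keyLabel(w5), "indeterminate")
  expect_length(keyCandidates(w5), 3)
  expect_identical(pathString(w5), "1?")

  # length exactly on the couplet-2 split
  l125 <- classifyMicroscopy(4.9, 12.5, "narrowly_amygdaliform", 4, "sparse")
  expect_identical(keyLabel(l125), "indeterminate")
  expect_identical(pathString(l125), "1a→2?")

  # conflicting characters: long spores but abundant gloeocystidia
  conflict <- classifyMicroscopy(5.2, 12.3, "narrowly_subamygdaliform",
                                 2.0, "abundant")
  expect_identical(keyLabel(conflict), "indeterminate")

  # unknown characters never guess
  unk <- classifyMicroscopy(4.5, 12.0, "other", NA, "unknown")
  expect_identical(keyLabel(unk), "indeterminate")
})

test_that("classification is deterministic and fully audited", {
  a <- classifyMicroscopy(4.87, 12.29, "narrowly_amygdaliform", 3.5,
                          "sparse")
  b <- classifyMicroscopy(4.87, 12.29, "narrowly_amygdaliform", 3.5,
                          "sparse")
  expect_identical(keyLabel(a), keyLabel(b))
  expect_identical(keyPath(a), keyPath(b))
  expect_identical(keyCandidates(a), keyLabel(a))
})

test_that("every reachable leaf of the key is exercised", {
  cases <- list(
    list(4.8, 12.9, "narrowly_amygdaliform", 4.0, "sparse"),     # 2a
    list(4.8, 12.2, "ellipsoid_blunt", 1.0, "abundant"),         # 3a
    list(4.8, 12.2, "narrowly_amygdaliform", 4.0, "sparse"),     # 3b
    list(5.2, 11.9, "ellipsoid_blunt", 1.0, "abundant"),         # 4a
    list(5.2, 12.6, "narrowly_amygdaliform", 4.0, "sparse"),     # 5a
    list(5.2, 12.6, "narrowly_subamygdaliform", 1.5, "sparse"))  # 5b
  leaves <- vapply(cases, function(cs)
    utils::tail(keyPath(do.call(classifyMicroscopy, cs)), 1), character(1))
  expect_setequal(leaves, c("2a", "3a", "3b", "4a", "5a", "5b"))
  labels <- vapply(cases, function(cs)
    keyLabel(do.call(classifyMicroscopy, cs)), character(1))
  expect_false(any(labels == "indeterminate"))
})

test_that("simulated preset populations are not misrouted", {
  rates <- sapply(c("pulverulentus", "mediterraneensis", "poikilochromus"),
    function(sp) {
      cfg <- speciesPreset(sp, pCollections = 600, mBasidiomes = 10,
                           nPerBasidiome = 5, seed = 17)
      pop <- samplePopulation(cfg)
      feats <- data.frame(
        avg_width_um = tapply(pop$width_um, pop$collection_id, mean),
        avg_length_um = tapply(pop$length_um, pop$collection_id, mean),
        depression_pct = 100 * tapply(pop$concavity, pop$collection_id,
                                      mean))
      chars <- SporeHull:::speciesKeyCharacters(sp)
      feats$dominant_shape <- chars$shape
      feats$gloeocystidia <- chars$gloeo
      out <- classifyFeatures(feats)
      modal <- names(which.max(table(out$key_label)))
      expect_identical(modal, sp)
      mean(!out$key_label %in% c(sp, "indeterminate"))
    })
  expect_true(all(rates < 0.05))
})
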