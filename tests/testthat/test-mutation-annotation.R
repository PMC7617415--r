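test_that("BRAF codons map to their kinase-activity classes", {
  rules <- ras_rules()
  expect_equal(classify_braf(c(600, 594, 469, 250)),
               c("class1", "class3", "class2", "unclassified"))
  # every listed codon maps to exactly one class
  all_codons <- c(rules$braf$class1, rules$braf$class2, rules$braf$class3)
  cls <- classify_braf(all_codons)
  expect_equal(cls, c(rep("class1", length(rules$braf$class1)),
                      rep("class2", length(rules$braf$class2)),
                      rep("class3", length(rules$braf$class3))))
  # non-missense consequences are never class-assigned
  expect_equal(classify_braf(600, "nonsense"), "unclassified")
  expect_equal(classify_braf(600, "frameshift"), "unclassified")
})

test_that("domain A coincides with class 1 for missense variants", {
  expect_equal(classify_braf_domain(c(600, 594, 466)), c("A", "B", "C"))
  codons <- c(460:475, 580:605, 250)
  dom <- classify_braf_domain(codons)
  cls <- classify_braf(codons)
  expect_equal(dom == "A", cls == "class1")
})

test_that("KRAS/NRAS/NF1 variants classify as typical/atypical drivers", {
  expect_equal(
    classify_ras_pathway(c("KRAS", "KRAS", "NRAS", "NF1", "NF1", "KRAS"),
                         c(19, 12, 12, 500, 500, 25),
                         c("missense", "missense", "missense", "missense",
                           "nonsense", "missense")),
    c("atypical_ras", "kras_typical", "atypical_ras", "non_driver",
      "atypical_ras", "non_driver"))
  # synonymous changes are never drivers
  expect_equal(classify_ras_pathway("KRAS", 12, "synonymous"), "non_driver")
  expect_error(classify_ras_pathway("BRAF", 600), "BRAF")
})

test_that("NF1 splice handling follows the configurable truncating set", {
  expect_equal(classify_ras_pathway("NF1", 100, "splice"), "atypical_ras")
  rules_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nf1:", "  truncating_consequences: [nonsense, frameshift]"),
             rules_file)
  rules <- ras_rules(rules_file)
  expect_equal(classify_ras_pathway("NF1", 100, "splice", rules), "non_driver")
})

test_that("rule tables load from config and enforce disjointness", {
  f <- system.file("extdata", "classification_rules.yaml", package = "rasco")
  expect_equal(unclass(ras_rules(f))[1:4], unclass(ras_rules())[1:4])
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("braf:", "  class2: [600, 464]"), bad)
  expect_error(ras_rules(bad), "disjoint")
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("braf:", "  klass2: [464]"), bad2)
  expect_error(ras_rules(bad2), "klass2")
})

test_that("tumors roll up to class, domain and additional-Ras flags", {
  # class 3 with two atypical KRAS and an NRAS mutation
  v <- data.frame(sample_id = "t1",
                  gene = c("BRAF", "KRAS", "KRAS", "NRAS"),
                  protein_change = c("G466V", "V14L", "D33E", "G12V"))
  rec <- annotate_tumor(v)
  expect_equal(rec$braf_class, "class3")
  expect_true(rec$additional_ras)
  expect_true(rec$additional_ras_atypical)

  # V600E alone: class 1, no additional Ras
  rec <- annotate_tumor(data.frame(sample_id = "t2", gene = "BRAF",
                                   protein_change = "V600E"))
  expect_equal(rec$braf_class, "class1")
  expect_equal(rec$braf_domain, "A")
  expect_false(rec$additional_ras)
  expect_false(rec$additional_ras_atypical)

  # co-occurring class 2 and class 3 mutations: multi-class, full list kept
  v <- data.frame(sample_id = "t3", gene = c("BRAF", "BRAF"),
                  protein_change = c("D594G", "G469V"))
  rec <- annotate_tumor(v)
  expect_equal(rec$braf_class, "multiple")
  expect_equal(rec$braf_classes, "class2,class3")

  expect_error(
    annotate_tumor(data.frame(sample_id = c("a", "b"), gene = "BRAF",
                              protein_change = "V600E")),
    "single sample")
})

test_that("annotation is invariant to variant order and atypical implies additional", {
  set.seed(11)
  genes <- c("BRAF", "KRAS", "NRAS", "NF1")
  pcs <- list(BRAF = c("V600E", "G469V", "D594G", "R250Q"),
              KRAS = c("G12D", "L19F", "A146T"),
              NRAS = c("G12V", "Q61H"),
              NF1 = c("R100*", "T50A"))
  for (i in 1:25) {
    g <- sample(genes, sample(1:5, 1), replace = TRUE)
    v <- data.frame(sample_id = "s",
                    gene = g,
                    protein_change = vapply(g, function(gg) {
                      sample(pcs[[gg]], 1)
                    }, character(1)))
    a <- annotate_tumor(v)
    b <- annotate_tumor(v[sample(nrow(v)), , drop = FALSE])
    expect_equal(a, b)
    if (a$additional_ras_atypical) expect_true(a$additional_ras)
  }
})

test_that("cohort annotation matches a brute-force recount of the raw table", {
  sim <- simulate_cohort(400, seed = 3)
  ann <- annotate_cohort(sim$mutations, sim$clinical)
  # independent recount: a tumor carries class `cls` iff any BRAF missense
  # variant falls in that class's codon set (checked via braf_classes so
  # multi-class tumors count under every class they carry)
  for (cls in c("class1", "class2", "class3")) {
    rule_codons <- ras_rules()$braf[[cls]]
    by_hand <- vapply(split(sim$mutations, sim$mutations$sample_id),
                      function(v) {
                        p <- parse_protein_change(v$protein_change)
                        any(v$gene == "BRAF" & p$consequence == "missense" &
                              p$codon %in% rule_codons)
                      }, logical(1))
    got <- ann$braf_classes[match(names(by_hand), ann$sample_id)]
    carries <- vapply(strsplit(got, ","), function(z) cls %in% z, logical(1))
    expect_equal(unname(by_hand), carries)
  }
  # additional-Ras flag recount
  ras_by_hand <- vapply(split(sim$mutations, sim$mutations$sample_id),
                        function(v) {
                          v <- v[v$gene %in% c("KRAS", "NRAS", "NF1"), ,
                                 drop = FALSE]
                          if (nrow(v) == 0) return(FALSE)
                          p <- parse_protein_change(v$protein_change)
                          any(classify_ras_pathway(v$gene, p$codon,
                                                   p$consequence) != "non_driver")
                        }, logical(1))
  expect_equal(unname(ras_by_hand),
               ann$additional_ras[match(names(ras_by_hand), ann$sample_id)])
  # samples without somatic mutations in the table are BRAF wild-type
  expect_setequal(ann$sample_id, sim$clinical$sample_id)
  no_mut <- setdiff(sim$clinical$sample_id, sim$mutations$sample_id)
  expect_true(all(ann$braf_class[ann$sample_id %in% no_mut] == "wild_type"))
})
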