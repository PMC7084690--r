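test_that("a minimal PDB fixture parses to atoms without a cell", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"))
  m <- read_structure(p)
  expect_equal(nrow(m$atoms), 3)
  expect_null(m$cell)
  expect_setequal(m$atoms$elety, c("N", "CA", "C"))
  expect_equal(sort(unique(m$atoms$element)), c("C", "N"))
})

test_that("CRYST1 with a trigonal space group yields six symmetry operators", {
  cr <- "CRYST1   48.300   48.300   60.400  90.00  90.00 120.00 P 31 2 1     6"
  p <- write_mini_pdb(tempfile(fileext = ".pdb"), cryst1 = cr)
  m <- read_structure(p)
  expect_equal(m$cell, c(48.3, 48.3, 60.4, 90, 90, 120))
  expect_equal(length(m$sym_ops), 6)
  # first operator is the identity
  expect_equal(m$sym_ops[[1]]$R, diag(3))
  expect_equal(m$sym_ops[[1]]$t, c(0, 0, 0))
})

test_that("mmCIF and PDB encodings of the same model are equivalent", {
  cr <- "CRYST1   48.300   48.300   60.400  90.00  90.00 120.00 P 31 2 1     6"
  mp <- read_structure(write_mini_pdb(tempfile(fileext = ".pdb"), cr))
  mc <- read_structure(write_mini_cif(tempfile(fileext = ".cif")))
  expect_equal(mp$atoms[, c("chain", "resno", "elety", "x", "y", "z")],
               mc$atoms[, c("chain", "resno", "elety", "x", "y", "z")])
  expect_equal(mp$cell, mc$cell)
  expect_equal(length(mp$sym_ops), length(mc$sym_ops))
})

test_that("unknown space groups name the supported set", {
  expect_error(space_group_ops("Q 42"), "supported")
  expect_equal(length(space_group_ops("P 1")), 1)
  expect_equal(length(space_group_ops("P 21 21 21")), 4)
  # symbol normalization tolerates spacing and underscores
  expect_equal(length(space_group_ops("P3_1_21")), 6)
})

test_that("symmetry operators are proper crystallographic transforms", {
  for (sg in c("P 31 2 1", "P 21 21 21", "C 2")) {
    ops <- space_group_ops(sg)
    for (op in ops) {
      expect_equal(abs(det(op$R)), 1)
      # group closure under composition modulo lattice translations
      comp <- ops[[1]]$R %*% op$R
      expect_true(all(comp %in% -1:1))
    }
  }
})

test_that("structures round-trip through the PDB writer", {
  g <- gen_beta_dimer(list(c(8, 10), c(10, 8)))
  p <- tempfile(fileext = ".pdb")
  write_structure(g$model, p)
  back <- read_structure(p)
  expect_equal(nrow(back$atoms), nrow(g$model$atoms))
  ord <- function(at) at[order(at$chain, at$resno, at$elety),
                         c("x", "y", "z")]
  expect_equal(as.matrix(ord(back$atoms)), as.matrix(ord(g$model$atoms)),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("altlocs resolve to the highest-occupancy copy", {
  lines <- c(
    sprintf(paste0("ATOM  %5d  %-3s%s%3s %s%4d    ",
                   "%8.3f%8.3f%8.3f%6.2f%6.2f          %2s"),
            1:2, "CA", c("A", "B"), "ALA", "A", 1,
            c(0, 5), 0, 0, c(0.4, 0.6), 10, "C"),
    "END")
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  m <- read_structure(p)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$x, 5)
})
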