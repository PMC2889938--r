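# Kinetic-model loading, structural validation, rate compilation and SBML export.

test_that("the bundled NF-kB module has the documented structure", {
  m <- fx_model()
  expect_equal(nrow(m$species), 24)
  expect_equal(length(m$reactions), 72)
  expect_equal(sum(m$species$clamped), 1)
  expect_equal(m$species$name[m$species$clamped], "IKK")
  expect_setequal(unique(m$species$compartment), c("cytoplasm", "nucleus"))
  # declared NF-kB moiety verified in the stoichiometry left null space
  N <- nfkblink:::effective_stoichiometry(m)
  w <- nfkblink:::moiety_weight_vector(m, nfkblink:::find_moiety(m, "NFkB_total"))
  expect_lt(max(abs(w %*% N)), 1e-12)
})

test_that("arity and reference validation reject malformed configs", {
  # association with one reactant
  expect_error(load_model(write_tiny_model(
    "  - {type: association, reactants: [A], products: [C], k: 2}")),
    "arity")
  # unknown species
  expect_error(load_model(write_tiny_model(
    "  - {type: association, reactants: [A, Z], products: [C], k: 2}")),
    "unknown species")
  # non-positive rate
  expect_error(load_model(write_tiny_model(
    "  - {type: association, reactants: [A, B], products: [C], k: 0}")),
    "rate constant")
  # transport must cross compartments
  expect_error(load_model(write_tiny_model(
    "  - {type: transport, reactants: [A], products: [B], k: 1}")),
    "arity|compartment")
  # a species in no reaction and not clamped
  expect_error(load_model(write_tiny_model(
    "  - {type: association, reactants: [A, B], products: [C], k: 2}\n  - {type: degradation, reactants: [C], k: 1}",
    species_yaml = "
species:
  - {name: A, compartment: cytoplasm, init: 1}
  - {name: B, compartment: cytoplasm, init: 3}
  - {name: C, compartment: cytoplasm, init: 0}
  - {name: D, compartment: cytoplasm, init: 0}
")), "no reaction")
  # an undeclared moiety that is not conserved
  path <- write_tiny_model(
    "  - {type: association, reactants: [A, B], products: [C], k: 2}\nmoieties:\n  - name: bogus\n    members: {A: 1}")
  expect_error(load_model(path), "not conserved")
})

test_that("mass-action rates follow k times reactant concentrations", {
  m <- load_model(write_tiny_model(
    "  - {type: association, reactants: [A, B], products: [C], k: 2}"))
  comp <- compile_rates(m)
  d <- comp$derivs(0, c(A = 1, B = 3, C = 0), function(t) numeric(0))
  expect_equal(d, c(-6, -6, 6))
  # template-modulated synthesis vanishes with its template
  m2 <- load_model(write_tiny_model(
    "  - {type: synthesis, products: [C], modifiers: [A], k: 5}\n  - {type: degradation, reactants: [A], k: 1}\n  - {type: degradation, reactants: [B], k: 1}"))
  comp2 <- compile_rates(m2)
  d2 <- comp2$derivs(0, c(A = 0, B = 1, C = 0), function(t) numeric(0))
  expect_equal(d2[3], 0)
  d3 <- comp2$derivs(0, c(A = 2, B = 1, C = 0), function(t) numeric(0))
  expect_equal(d3[3], 10)
})

test_that("cross-compartment transport conserves volume-weighted amounts", {
  m <- load_model(write_tiny_model(
    "  - {type: transport, reactants: [A], products: [C], k: 1}",
    species_yaml = "
species:
  - {name: A, compartment: cytoplasm, init: 1}
  - {name: C, compartment: nucleus, init: 0}
"))
  comp <- compile_rates(m)
  d <- comp$derivs(0, c(A = 2, C = 0), function(t) numeric(0))
  # kv = 0.5: the nucleus receives at 1/kv per unit flux
  expect_equal(d, c(-2, 4))
  # volume-weighted total is unchanged: dA + kv * dC = 0
  expect_equal(d[1] + 0.5 * d[2], 0)
})

test_that("compiled derivatives of the full model match a finite-difference oracle", {
  m <- fx_model()
  comp <- compile_rates(m)
  y <- stats::setNames(m$species$init, m$species$name)
  input <- function(t) rep(1e-4, length(t))
  d <- comp$derivs(0, y, input)
  # central difference of a short integrator step around t = 0
  h <- 1e-8
  fun <- function(t, y, parms) list(comp$derivs(t, y, input))
  out <- deSolve::lsoda(y, c(0, h, 2 * h), fun, parms = NULL,
                        rtol = 1e-12, atol = 1e-18)
  fd <- (out[3, -1] - out[1, -1]) / (2 * h)
  free <- !m$species$clamped
  scale <- max(abs(d))
  expect_lt(max(abs(fd[free] - d[free])) / scale, 1e-5)
})

test_that("SBML export is well-formed and mirrors the reaction table", {
  m <- fx_model()
  path <- tempfile(fileext = ".sbml")
  export_sbml(m, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  expect_equal(length(xml2::xml_find_all(doc, "//s:species", ns)), 24)
  expect_equal(length(xml2::xml_find_all(doc, "//s:reaction", ns)), 72)
  expect_equal(length(xml2::xml_find_all(doc, "//s:compartment", ns)), 2)
  # the clamped input is exported as a boundary species
  ikk <- xml2::xml_find_first(doc, "//s:species[@id='IKK']", ns)
  expect_equal(xml2::xml_attr(ikk, "boundaryCondition"), "true")
  # every reaction carries a kinetic law
  expect_equal(length(xml2::xml_find_all(doc, "//s:kineticLaw", ns)), 72)
})
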