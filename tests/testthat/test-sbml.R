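sbmlHeader <- paste0(
  '<?xml version="1.0" encoding="UTF-8"?>',
  '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
  'level="3" version="1">')

writeTempSbml <- function(body) {
  path <- tempfile(fileext = ".xml")
  writeLines(c(sbmlHeader, body, "</sbml>"), path)
  path
}

test_that("a minimal mass-action model imports as one state equation", {
  path <- writeTempSbml('
    <model id="decay">
      <listOfSpecies>
        <species id="A" compartment="c" initialConcentration="2"/>
      </listOfSpecies>
      <listOfParameters><parameter id="k" value="0.5"/></listOfParameters>
      <listOfReactions>
        <reaction id="deg">
          <listOfReactants><speciesReference species="A"/></listOfReactants>
          <kineticLaw>
            <math xmlns="http://www.w3.org/1998/Math/MathML">
              <apply><times/><ci>k</ci><ci>A</ci></apply>
            </math>
          </kineticLaw>
        </reaction>
      </listOfReactions>
    </model>')
  m <- readSBML(path)
  expect_identical(speciesNames(m), "A")
  expect_equal(m@parameters, c(k = 0.5))
  # dA/dt = -k A: check against the closed form
  tr <- simulateModel(m, settings = SimulationSettings(horizon = 2,
                                                       times = c(0, 2)))
  expect_equal(unname(tr[2, "A"]), 2 * exp(-0.5 * 2), tolerance = 1e-5)
})

test_that("unsupported constructs are rejected by name", {
  ev <- writeTempSbml('
    <model id="m">
      <listOfEvents><event id="e"/></listOfEvents>
      <listOfSpecies><species id="A" initialConcentration="1"/></listOfSpecies>
    </model>')
  expect_error(readSBML(ev), "events")
  rules <- writeTempSbml('
    <model id="m">
      <listOfRules><rateRule variable="A"/></listOfRules>
      <listOfSpecies><species id="A" initialConcentration="1"/></listOfSpecies>
    </model>')
  expect_error(readSBML(rules), "rules")
  nokl <- writeTempSbml('
    <model id="m">
      <listOfSpecies><species id="A" initialConcentration="1"/></listOfSpecies>
      <listOfReactions><reaction id="r1">
        <listOfReactants><speciesReference species="A"/></listOfReactants>
      </reaction></listOfReactions>
    </model>')
  expect_error(readSBML(nokl), "lacks a kinetic law")
})

test_that("local kinetic-law parameters are promoted, not dropped", {
  path <- writeTempSbml('
    <model id="m">
      <listOfSpecies>
        <species id="A" initialConcentration="1"/>
      </listOfSpecies>
      <listOfReactions>
        <reaction id="deg">
          <listOfReactants><speciesReference species="A"/></listOfReactants>
          <kineticLaw>
            <math xmlns="http://www.w3.org/1998/Math/MathML">
              <apply><times/><ci>kloc</ci><ci>A</ci></apply>
            </math>
            <listOfLocalParameters>
              <localParameter id="kloc" value="0.25"/>
            </listOfLocalParameters>
          </kineticLaw>
        </reaction>
      </listOfReactions>
    </model>')
  m <- readSBML(path)
  expect_true("deg_kloc" %in% names(m@parameters))
  expect_equal(m@parameters[["deg_kloc"]], 0.25)
  expect_identical(all.vars(m@reactions[[1]]$rate), c("deg_kloc", "A"))
})

test_that("boundary species become parameters, not states", {
  path <- writeTempSbml('
    <model id="m">
      <listOfSpecies>
        <species id="A" initialConcentration="1"/>
        <species id="E" initialConcentration="5" boundaryCondition="true"/>
      </listOfSpecies>
      <listOfParameters><parameter id="k" value="0.1"/></listOfParameters>
      <listOfReactions>
        <reaction id="r">
          <listOfReactants><speciesReference species="A"/></listOfReactants>
          <kineticLaw>
            <math xmlns="http://www.w3.org/1998/Math/MathML">
              <apply><times/><ci>k</ci><ci>E</ci><ci>A</ci></apply>
            </math>
          </kineticLaw>
        </reaction>
      </listOfReactions>
    </model>')
  m <- readSBML(path)
  expect_identical(speciesNames(m), "A")
  expect_equal(m@parameters[["E"]], 5)
})

test_that("the fixture round-trips through SBML with identical dynamics", {
  fx <- makeReducedErbbModel()
  path <- tempfile(fileext = ".xml")
  writeSBML(fx, path)
  m2 <- readSBML(path)
  expect_identical(sort(speciesNames(m2)), sort(speciesNames(fx)))
  expect_equal(m2@parameters[names(fx@parameters)], fx@parameters)
  s <- SimulationSettings()
  for (ov in list(c(HRG = 1, Per = 0), c(HRG = 1, Per = 100))) {
    t1 <- simulateModel(fx, params = ov, settings = s)
    t2 <- simulateModel(m2, params = ov, settings = s)
    expect_lt(max(abs(t1[, speciesNames(fx)] - t2[, speciesNames(fx)])),
              1e-6)
  }
})

test_that("MathML e-notation and nested arithmetic parse correctly", {
  path <- writeTempSbml('
    <model id="m">
      <listOfSpecies><species id="A" initialConcentration="1"/></listOfSpecies>
      <listOfParameters><parameter id="Km" value="2"/></listOfParameters>
      <listOfReactions>
        <reaction id="r">
          <listOfReactants><speciesReference species="A"/></listOfReactants>
          <kineticLaw>
            <math xmlns="http://www.w3.org/1998/Math/MathML">
              <apply><divide/>
                <apply><times/>
                  <cn type="e-notation">1.5<sep/>-2</cn><ci>A</ci>
                </apply>
                <apply><plus/><ci>Km</ci><ci>A</ci></apply>
              </apply>
            </math>
          </kineticLaw>
        </reaction>
      </listOfReactions>
    </model>')
  m <- readSBML(path)
  rate <- m@reactions[[1]]$rate
  expect_equal(eval(rate, list(A = 1, Km = 2)), 0.015 / 3)
})
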