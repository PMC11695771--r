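## Shared fixtures, built lazily and cached for the whole test run.
## Everything is generated in code; the generator is deterministic.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

toy_single <- function() {
  fixture("toy_single", function() generate_toy_sporulation_model())
}

toy_vegetative <- function() {
  fixture("toy_vegetative", function()
    configure_medium(toy_single(), toy_glutamate_medium(toy_single())))
}

toy_two_default <- function() {
  fixture("toy_two_default", function() build_two_cell_toy(toy_single()))
}

toy_two_no_transport <- function() {
  fixture("toy_two_no_transport", function()
    build_two_cell_toy(toy_single(),
                       scenario_flags(ndp_ntp_transport = FALSE,
                                      atp_transport = FALSE)))
}

toy_two_shuttle <- function() {
  fixture("toy_two_shuttle", function()
    build_two_cell_toy(toy_single(), scenario_flags(atp_transport = FALSE)))
}

veg_growth <- function() {
  fixture("veg_growth", function() maximize_growth(toy_vegetative()))
}

shuttle_growth <- function() {
  fixture("shuttle_growth", function() maximize_growth(toy_two_shuttle()))
}

shuttle_fluxes <- function() {
  fixture("shuttle_fluxes", function() {
    r <- shuttle_growth()
    v <- parsimonious_solution(toy_two_shuttle(), r$mu_max)
    attr(v, "mu") <- r$mu_max
    v
  })
}

ilvc_analysis <- function() {
  fixture("ilvc_analysis", function()
    dependency_analysis(toy_two_shuttle(), "ilvC", cell = "forespore"))
}
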