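# Small instances built in code for fast solver-backed tests.

# Two areas, two temporary, two general hospitals; numbers tiny enough for
# the pure-R backend and for hand-checking.
tiny_instance <- function(vehicles = 10L, helicopters = 10L) {
  evac_instance(
    areas = c("I1", "I2"), temp_hospitals = c("J1", "J2"),
    general_hospitals = c("K1", "K2"),
    casualties = matrix(c(4, 2,   # serious
                          6, 5),  # moderate
                        nrow = 2, dimnames = list(c("I1", "I2"),
                                                  c("serious", "moderate"))),
    road_times = matrix(c(0.5, 1.0,
                          0.8, 0.4), nrow = 2, byrow = TRUE,
                        dimnames = list(c("I1", "I2"), c("J1", "J2"))),
    air_times = matrix(c(0.6, 0.7,
                         0.65, 0.6), nrow = 2, byrow = TRUE,
                       dimnames = list(c("J1", "J2"), c("K1", "K2"))),
    fleet = fleet_spec(vehicles, helicopters, 6L, 12L),
    temp_capacity = 20,
    general_capacity = matrix(c(10, 15,
                                10, 15), nrow = 2, byrow = TRUE,
                              dimnames = list(c("K1", "K2"),
                                              c("serious", "moderate"))))
}

# One area, one temporary, one general hospital: the optimum is forced, so
# the objective has a closed form used as an independent oracle.
single_chain_instance <- function(qs = 3L, qm = 5L, t_road = 0.9,
                                  t_air = 0.6) {
  evac_instance(
    areas = "I1", temp_hospitals = "J1", general_hospitals = "K1",
    casualties = matrix(c(qs, qm), nrow = 1,
                        dimnames = list("I1", c("serious", "moderate"))),
    road_times = matrix(t_road, 1, 1, dimnames = list("I1", "J1")),
    air_times = matrix(t_air, 1, 1, dimnames = list("J1", "K1")),
    fleet = fleet_spec(10L, 10L, 6L, 12L),
    temp_capacity = 100,
    general_capacity = matrix(c(50, 50), nrow = 1,
                              dimnames = list("K1", c("serious", "moderate"))))
}

# Closed-form objective of the single-chain instance: all casualties must
# traverse the unique road and air arcs.
single_chain_objective <- function(qs, qm, t_road, t_air, factor = 0.2) {
  road <- qs * 2 * t_road * 0.8 * 2 + qm * 2 * t_road * 0.2 * 1
  air <- qs * 2 * t_air * factor * 0.8 * 2 + qm * 2 * t_air * factor * 0.2 * 1
  road + air
}

# Seeded small random instances for cross-formulation and cross-method
# checks; casualty counts kept small so fleets of <= 12 tools suffice.
small_random_params <- function(seed, n_areas = 3L, n_temp = 2L,
                                n_general = 2L, capacity_slack = 1.2) {
  generator_params(n_areas, n_temp, n_general, seed = seed,
                   casualty_range = list(serious = c(1L, 4L),
                                         moderate = c(2L, 6L)),
                   road_time_range = c(0.4, 2.0),
                   air_time_range = c(0.5, 0.8),
                   capacity_slack = capacity_slack)
}

small_random_instance <- function(seed, vehicles = 12L, helicopters = 12L,
                                  ...) {
  inst <- generate_instance(small_random_params(seed, ...))
  inst$fleet <- fleet_spec(vehicles, helicopters,
                           inst$fleet$vehicle_capacity,
                           inst$fleet$helicopter_capacity)
  inst
}

expect_optimal <- function(sol) {
  expect_identical(sol$solver_status, "optimal")
  invisible(sol)
}

# Shared solved fixtures, computed once per test run.
lushan_nominal_solution <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- solve_static(lushan_instance())
    cache
  }
})
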