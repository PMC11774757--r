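# Shipped model fixtures.
#
# Small, fully specified models used by the verification suite, the tests
# and the examples.  The membrane-phosphorylation slab is the analytic
# benchmark: protein A is phosphorylated at the membrane (z = 0) at rate
# k_kin * A|_membrane (a first-order surface flux) and dephosphorylated
# throughout the volume at rate k_p * Ap; both forms share one diffusion
# coefficient, so A + Ap is conserved.

#' Parameters of the slab-phosphorylation benchmark
#'
#' @param L slab thickness (um); the membrane sits at z = 0.
#' @param D diffusivity of both protein forms (um^2 s^-1).
#' @param k_kin membrane phosphorylation rate constant (um s^-1),
#'   first-order in the membrane trace of the unphosphorylated form.
#' @param k_p volume dephosphorylation rate (s^-1).
#' @param A_tot total protein concentration (uM), initially all
#'   unphosphorylated and uniform.
#' @return a `slab_problem` list.
#' @export
slab_problem <- function(L = 1, D = 10, k_kin = 1, k_p = 1, A_tot = 1) {
  stopifnot(L > 0, D > 0, k_kin >= 0, k_p > 0, A_tot > 0)
  structure(list(L = L, D = D, k_kin = k_kin, k_p = k_p, A_tot = A_tot),
            class = "slab_problem")
}

#' Slab-phosphorylation model on an n-per-edge mesh
#'
#' 1 volume compartment, 1 surface, 2 volume species, 1 surface reaction
#' (phosphorylation flux at the membrane) and 1 volume reaction
#' (dephosphorylation).
#'
#' @param problem a [slab_problem()].
#' @param n mesh resolution (boxes per edge of the `L x L x L` slab).
#' @return a validated `rd_model`.
#' @export
slab_model <- function(problem = slab_problem(), n = 4) {
  mesh <- generate_slab(problem$L, problem$L, problem$L, n)
  cfg <- list(
    compartments = list(
      list(name = "cytosol", kind = "volume", tag = 1),
      list(name = "membrane", kind = "surface", tag = 2, borders = list("cytosol"))),
    species = list(
      list(name = "A", compartment = "cytosol", D = problem$D,
           initial = problem$A_tot),
      list(name = "Ap", compartment = "cytosol", D = problem$D, initial = 0)),
    parameters = list(
      list(name = "kkin", value = problem$k_kin, unit = "um/s"),
      list(name = "kp", value = problem$k_p, unit = "1/s")),
    reactions = list(
      list(name = "phosphorylation", type = "volume_surface",
           compartment = "membrane", rate = "kkin*A",
           stoich = list(A = -1, Ap = 1), rate_unit = "uM*um/s"),
      list(name = "dephosphorylation", type = "volume",
           compartment = "cytosol", rate = "kp*Ap",
           stoich = list(A = 1, Ap = -1), rate_unit = "uM/s")))
  validate_model(build_containers(cfg), mesh)
}

#' Closed A <-> B volume fixture
#'
#' Two equal-diffusivity species interconverting in one volume; A + B is
#' conserved pointwise, so the model admits conservation reduction.
#'
#' @param D diffusivity (um^2 s^-1).
#' @param kf,kr forward/backward rates (s^-1).
#' @param A0,B0 uniform initial concentrations (uM).
#' @param n mesh resolution.
#' @return a validated `rd_model`.
#' @export
ab_model <- function(D = 1, kf = 2, kr = 1, A0 = 1, B0 = 0, n = 2) {
  mesh <- generate_slab(1, 1, 1, n)
  cfg <- list(
    compartments = list(
      list(name = "cytosol", kind = "volume", tag = 1),
      list(name = "membrane", kind = "surface", tag = 2, borders = list("cytosol"))),
    species = list(
      list(name = "A", compartment = "cytosol", D = D, initial = A0),
      list(name = "B", compartment = "cytosol", D = D, initial = B0)),
    parameters = list(
      list(name = "kf", value = kf, unit = "1/s"),
      list(name = "kr", value = kr, unit = "1/s")),
    reactions = list(
      list(name = "interconversion", type = "volume", compartment = "cytosol",
           rate = "kf*A - kr*B", stoich = list(A = -1, B = 1),
           rate_unit = "uM/s")))
  validate_model(build_containers(cfg), mesh)
}

#' Volume <-> surface binding fixture
#'
#' A volume ligand C (uM) adsorbing to and desorbing from a membrane-bound
#' state S (molecules um^-2) on the slab membrane:
#' rate = `kon * C - koff * S` in molecules um^-2 s^-1.  Total molecules
#' (volume + surface) are conserved.
#'
#' @param D volume diffusivity (um^2 s^-1).
#' @param DS surface diffusivity (um^2 s^-1).
#' @param kon adsorption coefficient (molecules um^-2 s^-1 per uM).
#' @param koff desorption rate (s^-1).
#' @param C0 initial volume concentration (uM).
#' @param S0 initial surface density (molecules um^-2).
#' @param n mesh resolution.
#' @return a validated `rd_model`.
#' @export
binding_model <- function(D = 1, DS = 0.1, kon = 10, koff = 1,
                          C0 = 1, S0 = 0, n = 2) {
  mesh <- generate_slab(1, 1, 1, n)
  cfg <- list(
    compartments = list(
      list(name = "cytosol", kind = "volume", tag = 1),
      list(name = "membrane", kind = "surface", tag = 2, borders = list("cytosol"))),
    species = list(
      list(name = "C", compartment = "cytosol", D = D, initial = C0),
      list(name = "S", compartment = "membrane", D = DS, initial = S0)),
    parameters = list(
      list(name = "kon", value = kon, unit = "molecules/um^2/s/uM"),
      list(name = "koff", value = koff, unit = "1/s")),
    reactions = list(
      list(name = "binding", type = "volume_surface", compartment = "membrane",
           rate = "kon*C - koff*S", stoich = list(C = -1, S = 1),
           rate_unit = "molecules/um^2/s")))
  validate_model(build_containers(cfg), mesh)
}

#' Nested two-volume transport fixture
#'
#' Cytosol and organelle volumes exchanging a species across the organelle
#' membrane (a volume-surface-volume reaction with rate
#' `k * (Ca_cyto - Ca_org)` in uM um s^-1).
#'
#' @param dim 2 (nested disks) or 3 (nested spheres).
#' @param D diffusivity in both volumes (um^2 s^-1).
#' @param k membrane permeability (um s^-1).
#' @param h target mesh edge length (um).
#' @param C_cyto0,C_org0 initial concentrations (uM).
#' @return a validated `rd_model`.
#' @export
nested_transport_model <- function(dim = 2, D = 1, k = 1, h = 0.4,
                                   C_cyto0 = 1, C_org0 = 0) {
  mesh <- generate_nested(2, 1, h, dim = dim)
  cfg <- list(
    compartments = list(
      list(name = "cytosol", kind = "volume", tag = 1),
      list(name = "organelle", kind = "volume", tag = 2),
      list(name = "PM", kind = "surface", tag = 3, borders = list("cytosol")),
      list(name = "OM", kind = "surface", tag = 4,
           borders = list("cytosol", "organelle"))),
    species = list(
      list(name = "Ca_cyto", compartment = "cytosol", D = D, initial = C_cyto0),
      list(name = "Ca_org", compartment = "organelle", D = D, initial = C_org0)),
    parameters = list(
      list(name = "kperm", value = k, unit = "um/s")),
    reactions = list(
      list(name = "om_transport", type = "volume_surface_volume",
           compartment = "OM", rate = "kperm*(Ca_cyto - Ca_org)",
           stoich = list(Ca_cyto = -1, Ca_org = 1),
           rate_unit = "uM*um/s")))
  validate_model(build_containers(cfg), mesh)
}
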