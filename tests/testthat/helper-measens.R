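# Shared fixtures for the test suite: compact layouts and coarse meshes so
# every FEM test solves in seconds.  All geometry is generated in code.

coarse_res <- function(k = 1)
  mesh_resolution(k, h_xz = 6, h_y = 3, y_fine = 15)

# compact two-electrode pair in a small bath
tiny_two <- function() {
  list(layout = mea_layout("custom", electrodes = data.frame(
         id = c("A", "B"), x = c(-30, 30), z = 0, diameter = 24,
         role = c("excitation", "counter"))),
       domain = simulation_domain(c(-150, 150), c(0, 120), c(-80, 80)))
}

# compact collinear four-electrode constellation
tiny_four <- function() {
  list(layout = mea_layout("custom", electrodes = data.frame(
         id = c("E1", "E2", "E3", "E4"), x = c(-90, -30, 30, 90), z = 0,
         diameter = 24,
         role = c("excitation", "recording_pos", "recording_neg", "counter"))),
       domain = simulation_domain(c(-250, 250), c(0, 150), c(-100, 100)))
}

default_interfaces <- function()
  list(electrode = electrode_interface_params(), membrane = membrane_params())

# membrane made electrically transparent (vanishing film impedance)
transparent_membrane <- function()
  list(electrode = electrode_interface_params(),
       membrane = membrane_params(g_m = 1e9, c_m = 1))

uniform_materials <- function()
  material_props(cytoplasm = list(sigma = 1.57, eps_r = 77))
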