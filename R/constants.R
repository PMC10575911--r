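# Electromagnetic constants (CODATA 2018), SI units.
.eps0 <- 8.8541878128e-12   # vacuum permittivity, F/m
.mu0  <- 1.25663706212e-6   # vacuum permeability, H/m
.c0   <- 299792458          # speed of light, m/s
.eta0 <- 376.730313668      # free-space wave impedance, ohm

.pkg_env <- new.env(parent = emptyenv())
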