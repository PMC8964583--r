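#' @keywords internal
"_PACKAGE"

## Internal unit conventions: SI everywhere (m, Pa, N, s). The I/O and CLI
## layers speak lab units (um, kPa, nN) and convert at the boundary.

.um <- 1e-6
.kpa <- 1e3
.nn <- 1e-9

um_to_m <- function(x) x * .um
m_to_um <- function(x) x / .um
kpa_to_pa <- function(x) x * .kpa
nn_to_n <- function(x) x * .nn
n_to_nn <- function(x) x / .nn

## Coordinate convention (stated on all outputs): image origin top-left,
## x rightward along columns, y downward along rows; physical position of
## pixel (row i, col j) is ((j-1)*pixel_size, (i-1)*pixel_size).
COORD_CONVENTION <- "origin top-left; x rightward (columns); y downward (rows); position = pixel index * pixel_size"
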