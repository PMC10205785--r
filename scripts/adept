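#!/usr/bin/env bash
# Thin launcher for the installed package's command-line interface.
exec Rscript "$(Rscript -e 'cat(system.file("cli", "adept.R", package = "adept"))')" "$@"
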