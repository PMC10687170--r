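# Factor levels of the task's trial conditions (load-order: needed by
# several files' top-level constants).

SPEED_LEVELS <- c("fast", "slow")
DIRECTION_LEVELS <- c("down", "right", "up", "left")
PERTURBATION_LEVELS <- c("unperturbed", "towards", "away")
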