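# Constructed example of a C2 symmetry definition derived from a dimeric
# crystal structure (NCS mode): explicit virtual coordinate frames, an
# energy line reconstructing the dimer total as twice the master subunit's
# internal energy plus the single unique interface, and one translational +
# one rotational rigid-body degree of freedom along the frame x axis.
symmetry_name C2_ncs_example
total_subunits 2
E = 2*VRT0_base + 1*(VRT0_base:VRT1_base)
anchor 25
virtual_coordinates_start
xyz VRT0 0.1035485,-0.2974247,-0.9491134 0.9444017,0.3287938,0.0000000 3.6626788,5.0513324,-47.0664146
xyz VRT1 -0.1035485,0.2974247,0.9491134 -0.9444017,-0.3287938,0.0000000 3.6626788,5.0513324,-47.0664146
xyz VRT0_base 0.1035485,-0.2974247,-0.9491134 0.9444017,0.3287938,0.0000000 3.6626788,5.0513324,-47.0664146
xyz VRT1_base -0.1035485,0.2974247,0.9491134 -0.9444017,-0.3287938,0.0000000 3.6626788,5.0513324,-47.0664146
virtual_coordinates_stop
connect_virtual ROOTJUMP0 ROOT VRT0
connect_virtual ROOTJUMP1 ROOT VRT1
connect_virtual JUMP0 VRT0 VRT0_base
connect_virtual JUMP1 VRT1 VRT1_base
connect_virtual JUMP0_to_com VRT0_base SUBUNIT
connect_virtual JUMP1_to_com VRT1_base SUBUNIT
set_jump_group ROOTGROUP ROOTJUMP0 ROOTJUMP1
set_jump_group BASEGROUP JUMP0 JUMP1
set_jump_group COMGROUP JUMP0_to_com JUMP1_to_com
set_dof JUMP0_to_com x(21.28) angle_x
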