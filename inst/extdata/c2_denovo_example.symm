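# Constructed example of the de novo C2 symmetry definition: implicit
# frames from a transform recipe (a twofold rotation about z applied to the
# start frame), subunits initially at (50,0,0) and (-50,0,0) with fully
# randomizable orientations.
symmetry_name C2
total_subunits 2
E = 2*VRT0 + 1*(VRT0:VRT1)
anchor COM
recenter
slide_type SEQUENTIAL
slide_criteria_type CONTACT
slide_criteria_val 4.5
virtual_transforms_start
start -1.0000000,0.0000000,0.0000000 0.0000000,1.0000000,0.0000000 0.0000000,0.0000000,0.0000000
rot Rz 2
virtual_transforms_stop
connect_virtual ROOTJUMP0 ROOT VRT0
connect_virtual ROOTJUMP1 ROOT VRT1
connect_virtual BASEJUMP VRT0 SUBUNIT
connect_virtual BASEJUMP1 VRT1 SUBUNIT
set_jump_group BASEGROUP BASEJUMP BASEJUMP1
set_jump_group ROOTGROUP ROOTJUMP0 ROOTJUMP1
set_dof BASEJUMP x(50) angle_x(0:360) angle_y(0:360) angle_z(0:360)
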